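test_that("an identical planted segment is recovered at exact coordinates", {
  withr::with_seed(51, {
    seg <- random_dna(500, 0.4)
    cp <- paste0(random_dna(3000, 0.4), seg, random_dna(2500, 0.4))
    mt <- paste0(random_dna(4000, 0.45), seg, random_dna(3000, 0.45))
  })
  al <- local_align(cp, mt)
  expect_equal(nrow(al), 1L)
  expect_equal(al$q_start, 3001L)
  expect_equal(al$q_end, 3500L)
  expect_equal(al$s_start, 4001L)
  expect_equal(al$s_end, 4500L)
  expect_equal(al$identity, 1)
  expect_equal(al$strand, "+")
  expect_lt(al$evalue, 1e-5)
})

test_that("a long near-identical transfer is one hit with exact mismatch
           count", {
  withr::with_seed(52, {
    seg <- chars_(random_dna(5142, 0.4))
    mutated <- seg
    pos <- sample(100:5000, 5)
    for (p in pos) {
      mutated[p] <- sample(setdiff(c("A", "C", "G", "T"), mutated[p]), 1)
    }
    cp <- paste0(random_dna(2000, 0.4), paste(seg, collapse = ""),
                 random_dna(2000, 0.4))
    mt <- paste0(random_dna(2500, 0.45), paste(mutated, collapse = ""),
                 random_dna(2500, 0.45))
  })
  al <- local_align(cp, mt)
  expect_equal(nrow(al), 1L)
  expect_equal(al$n_mismatch, 5L)
  expect_equal(al$n_gaps, 0L)
  # local alignment may gain a few chance-matching flank bases at the ends
  expect_gte(al$aligned_length, 5142L)
  expect_lte(al$aligned_length, 5150L)
  expect_lte(abs(al$q_start - 2001L), 5)
  expect_lte(abs(al$s_start - 2501L), 5)
})

test_that("seed-and-extend score equals the Smith-Waterman optimum", {
  for (seed in 1:10) {
    pair <- make_homology_pair(seed)
    params <- alignment_params(evalue_max = 10)
    al <- local_align(pair$a, pair$b, params)
    expect_gt(nrow(al), 0)
    expect_equal(max(al$score), sw_oracle_score(pair$a, pair$b),
                 info = paste("seed", seed))
  }
})

test_that("reverse-strand homology is found with mirrored coordinates", {
  withr::with_seed(53, {
    seg <- random_dna(400, 0.4)
    cp <- paste0(random_dna(1000, 0.4), seg, random_dna(1000, 0.4))
    mt <- paste0(random_dna(1500, 0.45), revcomp(seg),
                 random_dna(1500, 0.45))
  })
  al <- local_align(cp, mt)
  expect_equal(nrow(al), 1L)
  expect_equal(al$strand, "-")
  expect_lte(abs(al$q_start - 1001L), 5)
  expect_lte(abs(al$s_start - 1501L), 5)
  expect_lte(abs(al$s_end - 1900L), 5)
})

test_that("query-subject swap mirrors coordinates and keeps scores", {
  withr::with_seed(54, {
    core <- random_dna(600, 0.4)
    a <- paste0(random_dna(800, 0.4), core, random_dna(800, 0.4))
    mutated <- chars_(core)
    for (p in sample(30:570, 8)) {
      mutated[p] <- sample(setdiff(c("A", "C", "G", "T"), mutated[p]), 1)
    }
    b <- paste0(random_dna(900, 0.45), paste(mutated, collapse = ""),
                random_dna(900, 0.45))
  })
  f <- local_align(a, b)
  r <- local_align(b, a)
  expect_equal(nrow(f), nrow(r))
  expect_equal(f$score, r$score)
  expect_equal(f$q_start, r$s_start)
  expect_equal(f$s_start, r$q_start)
})

test_that("random unrelated genomes yield no hits at E <= 1e-5", {
  for (seed in c(61, 62)) {
    withr::with_seed(seed, {
      a <- random_dna(10000, 0.45)
      b <- random_dna(10000, 0.38)
    })
    al <- local_align(a, b)
    expect_equal(nrow(al), 0L, info = paste("seed", seed))
  }
})

test_that("MTPT hits are ordered, binned and gene-annotated", {
  withr::with_seed(55, {
    segs <- lapply(c(1200, 700, 300), function(n) random_dna(n, 0.4))
    cp_seq <- paste0(random_dna(500, 0.4), segs[[1]], random_dna(400, 0.4),
                     segs[[2]], random_dna(400, 0.4), segs[[3]],
                     random_dna(500, 0.4))
    # degrade the second segment to ~85% identity
    deg <- chars_(segs[[2]])
    for (p in sample(10:690, 105)) {
      deg[p] <- sample(setdiff(c("A", "C", "G", "T"), deg[p]), 1)
    }
    mt_seq <- paste0(random_dna(2000, 0.45), segs[[1]],
                     random_dna(1500, 0.45), paste(deg, collapse = ""),
                     random_dna(1500, 0.45), revcomp(segs[[3]]),
                     random_dna(1000, 0.45))
  })
  cp <- molecule_table("cp", cp_seq, organelle = "plastid",
                       topology = "circular")
  mt <- molecule_table("mt1", mt_seq, organelle = "mito")
  s1_start <- 501L
  cp_features <- tibble::tibble(
    gene = c("geneA", "geneB"), molecule = "cp",
    start = c(s1_start + 99L, s1_start + 1100L),
    end = c(s1_start + 598L, s1_start + 1400L),
    strand = "+", type = "PCG",
    exons = list(tibble::tibble(start = 1, end = 1),
                 tibble::tibble(start = 1, end = 1)))
  hits <- find_mtpts(cp, mt, cp_features = cp_features)
  expect_gte(nrow(hits), 3L)
  expect_equal(hits$id[1:3], c("mtpt1", "mtpt2", "mtpt3"))
  expect_true(all(diff(hits$aligned_length) <= 0))
  expect_equal(hits$similarity_class[1], "eq100")
  h2 <- hits[hits$cp_start > 2000 & hits$cp_start < 2600, ]
  expect_equal(h2$similarity_class, "ge80lt90")
  h3 <- hits[hits$strand == "-", ]
  expect_gt(h3$mt_start[1], h3$mt_end[1])  # descending = reverse strand
  # geneA complete inside mtpt1, geneB partially overlapping -> fragment
  expect_match(hits$contained_genes[1], "geneA")
  expect_match(hits$contained_genes[1], "geneB-fra")
})

test_that("gene containment splits complete genes from fragments", {
  feats <- tibble::tibble(
    gene = c("psbJ", "psbL", "psbF", "psbE", "far"),
    molecule = "cp",
    start = c(200L, 450L, 40L, 480L, 900L),
    end = c(400L, 520L, 120L, 700L, 950L),
    strand = "+", type = "PCG",
    exons = list(1, 1, 1, 1, 1))
  g <- annotate_mtpt(100L, 500L, feats)
  expect_equal(g$gene, c("psbJ", "psbL", "psbF", "psbE"))
  expect_equal(g$status, c("complete", "fragment", "fragment", "fragment"))
})

test_that("homology union summary matches the per-base marking oracle", {
  for (seed in 1:5) {
    withr::with_seed(seed, {
      n_hits <- sample(3:12, 1)
      cp_s <- sample.int(9000, n_hits)
      cp_e <- pmin(10000L, cp_s + sample.int(800, n_hits))
      mt_s <- sample.int(19000, n_hits)
      mt_e <- pmin(20000L, mt_s + sample.int(800, n_hits))
    })
    hits <- tibble::tibble(cp_start = cp_s, cp_end = cp_e,
                           mt_molecule = "mt1", mt_start = mt_s,
                           mt_end = mt_e)
    cp <- tibble::tibble(id = "cp", length = 10000L)
    mt <- tibble::tibble(id = "mt1", length = 20000L)
    s <- summarize_homology(hits, cp, mt)
    expect_equal(s$total_cp_bp, union_bp_oracle(cp_s, cp_e, 10000L))
    expect_equal(s$total_mt_bp, union_bp_oracle(mt_s, mt_e, 20000L))
    expect_equal(s$cp_fraction,
                 round_half_up(100 * s$total_cp_bp / 10000, 2))
    # order independence
    perm <- sample(nrow(hits))
    s2 <- summarize_homology(hits[perm, ], cp, mt)
    expect_equal(s2$total_cp_bp, s$total_cp_bp)
    expect_equal(s2$total_mt_bp, s$total_mt_bp)
  }
})

test_that("repeat-region overlap is reported from the interval union", {
  hits <- tibble::tibble(cp_start = c(1L, 50L), cp_end = c(100L, 150L),
                         mt_molecule = "mt1", mt_start = 500L,
                         mt_end = 700L)
  cp <- tibble::tibble(id = "cp", length = 1000L)
  mt <- tibble::tibble(id = "mt1", length = 1000L)
  rr <- tibble::tibble(molecule = c("cp", "mt1"), start = c(120L, 600L),
                       end = c(400L, 650L))
  s <- summarize_homology(hits, cp, mt, rr)
  expect_equal(s$total_cp_bp, 150L)        # [1,100] u [50,150]
  expect_equal(s$cp_fraction, 15)
  expect_equal(s$repeat_region_cp_bp, 31L) # [120,150]
  expect_equal(s$repeat_region_mt_bp, 51L) # [600,650]
  expect_equal(s$raw_cp_bp, 201L)
})
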