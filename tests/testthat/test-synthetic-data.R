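small_config <- function(seed = 1L, ...) {
  sim_config(seed = seed,
             mt_lengths = c(20000L, 12000L), cp_length = 8000L,
             n_genes_mt = 4L, n_genes_cp = 3L,
             repeat_specs = tibble::tibble(
               length = c(600L, 250L),
               orientation = c("direct", "inverted"),
               placement = c("intra", "inter")),
             mtpt_specs = tibble::tibble(length = 500L, n_sub = 5L,
                                         n_indel = 0L),
             n_reads = 40L, ...)
}

test_that("the generator is byte-deterministic given a seed", {
  cfg <- small_config(7)
  s1 <- simulate_genomes(cfg)
  s2 <- simulate_genomes(cfg)
  expect_identical(s1$molecules$sequence, s2$molecules$sequence)
  expect_identical(s1$truth, s2$truth)
  f1 <- tempfile(fileext = ".fasta"); f2 <- tempfile(fileext = ".fasta")
  write_fasta(s1$molecules, f1); write_fasta(s2$molecules, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  r1 <- simulate_long_reads(s1$molecules, cfg)
  r2 <- simulate_long_reads(s2$molecules, cfg)
  expect_identical(r1$reads, r2$reads)
  s3 <- simulate_genomes(small_config(8))
  expect_false(identical(s1$molecules$sequence, s3$molecules$sequence))
})

test_that("planted repeats appear as exact copies at truth coordinates", {
  sim <- simulate_genomes(small_config(9))
  tr <- sim$truth$repeats
  expect_equal(nrow(tr), 2L)
  seqs <- setNames(sim$molecules$sequence, sim$molecules$id)
  for (r in seq_len(nrow(tr))) {
    c1 <- substr(seqs[[tr$molecule1[r]]], tr$start1[r], tr$end1[r])
    c2 <- substr(seqs[[tr$molecule2[r]]], tr$start2[r], tr$end2[r])
    if (tr$orientation[r] == "inverted") c2 <- revcomp(c2)
    expect_equal(c1, c2)
  }
  expect_equal(tr$molecule2[2], "mt2")   # inter-molecule placement
  # boundary guards: planted coordinates are the maximal repeat
  found <- find_repeats(sim$molecules, min_len = 100)
  found_direct <- found[found$orientation == "forward" &
                          found$length == 600L, ]
  expect_equal(found_direct$start1, tr$start1[1])
  expect_equal(found_direct$end2, tr$end2[1])
})

test_that("planted MTPT copies differ from their source exactly as
           specified", {
  sim <- simulate_genomes(small_config(10))
  mt <- sim$truth$mtpts
  expect_equal(nrow(mt), 1L)
  seqs <- setNames(sim$molecules$sequence, sim$molecules$id)
  src <- chars_(substr(seqs[["cp"]], mt$cp_start, mt$cp_end))
  dst <- chars_(substr(seqs[[mt$mt_molecule]], mt$mt_start, mt$mt_end))
  expect_equal(length(src), length(dst))   # no indels requested
  expect_equal(sum(src != dst), 5L)
  # indel-bearing spec: verify with an independent pairwise alignment
  cfg <- small_config(11)
  cfg$mtpt_specs <- tibble::tibble(length = 400L, n_sub = 3L, n_indel = 2L)
  sim2 <- simulate_genomes(cfg)
  m2 <- sim2$truth$mtpts
  seqs2 <- setNames(sim2$molecules$sequence, sim2$molecules$id)
  al <- Biostrings::pairwiseAlignment(
    substr(seqs2[["cp"]], m2$cp_start, m2$cp_end),
    substr(seqs2[[m2$mt_molecule]], m2$mt_start, m2$mt_end),
    type = "global")
  expect_equal(Biostrings::nmismatch(al), 3L)
  ins <- Biostrings::insertion(al)[[1]]
  del <- Biostrings::deletion(al)[[1]]
  expect_equal(sum(sum(Biostrings::width(ins))) +
                 sum(sum(Biostrings::width(del))), 2L)
})

test_that("planted genes are translatable open reading frames", {
  sim <- simulate_genomes(small_config(12))
  cds <- extract_cds(sim$molecules, sim$features)
  expect_equal(nrow(cds), 7L)
  for (i in seq_len(nrow(cds))) {
    s <- cds$sequence[i]
    expect_equal(nchar(s) %% 3, 0)
    expect_equal(substr(s, 1, 3), "ATG")
    codons <- substring(s, seq(1, nchar(s) - 2, 3), seq(3, nchar(s), 3))
    expect_equal(codons[length(codons)], "TAA")
    expect_false(any(codons[-length(codons)] %in% c("TAA", "TAG", "TGA")))
  }
})

test_that("error-free long reads are exact substrings of their source", {
  cfg <- small_config(13, sub_rate = 0, ins_rate = 0, del_rate = 0)
  sim <- simulate_genomes(cfg)
  lr <- simulate_long_reads(sim$molecules, cfg, n_reads = 25)
  expect_equal(nrow(lr$reads), 25L)
  expect_equal(sort(lr$origins$read_id), sort(lr$reads$read_id))
  seqs <- setNames(sim$molecules$sequence, sim$molecules$id)
  topo <- setNames(sim$molecules$topology, sim$molecules$id)
  for (i in seq_len(nrow(lr$reads))) {
    o <- lr$origins[i, ]
    expected <- as.character(mol_substr(seqs[[o$molecule]], o$start, o$end,
                                        topo[[o$molecule]]))
    if (o$strand == "-") expected <- revcomp(expected)
    expect_identical(lr$reads$sequence[i], expected)
  }
})

test_that("reads from circular molecules may cross the origin", {
  cfg <- small_config(14, sub_rate = 0, ins_rate = 0, del_rate = 0)
  cfg$read_mean <- 8000
  sim <- simulate_genomes(cfg)
  lr <- simulate_long_reads(sim$molecules, cfg, n_reads = 120)
  lens <- setNames(sim$molecules$length, sim$molecules$id)
  wraps <- lr$origins$end > lens[lr$origins$molecule]
  expect_gt(sum(wraps), 0)
  i <- which(wraps)[1]
  o <- lr$origins[i, ]
  seqs <- setNames(sim$molecules$sequence, sim$molecules$id)
  rot <- paste0(substr(seqs[[o$molecule]], o$start, lens[[o$molecule]]),
                substr(seqs[[o$molecule]], 1,
                       o$end - lens[[o$molecule]]))
  if (o$strand == "-") rot <- revcomp(rot)
  expect_identical(lr$reads$sequence[i], rot)
})

test_that("spanning-read mixtures follow the planted binomial", {
  toy <- withr::with_seed(91, {
    U <- random_dna(2000, 0.45); V <- random_dna(2500, 0.45)
    W <- random_dna(2000, 0.45); X <- random_dna(2000, 0.45)
    R <- random_dna(300, 0.45)
    molecule_table("m1", paste0(U, R, V, W, R, X))
  })
  rp <- tibble::tibble(repeat_id = "R1", molecule1 = "m1", start1 = 2001L,
                       end1 = 2300L, molecule2 = "m1", start2 = 7101L,
                       end2 = 7400L, orientation = "direct")
  sim <- simulate_spanning_reads(toy, rp, n = 2000, alt_fraction = 0.5,
                                 flank = 600L, seed = 42)
  n_alt <- sum(sim$truth$conformation == "alternative")
  expect_lt(abs(n_alt - 1000), 3 * sqrt(2000 * 0.25))
  # junction bookkeeping matches conformation labels
  expect_true(all(sim$truth$path[sim$truth$conformation == "major"] == "m1"))
  expect_true(all(sim$truth$path[sim$truth$conformation ==
                                   "alternative"] == "s1"))
})

test_that("RNA reads carry planted edits at the stated efficiency", {
  withr::with_seed(92, {
    cds <- tibble::tibble(
      gene = c("g1", "g2"), molecule = "mt1", organelle = "mito",
      strand = "+",
      sequence = c(random_dna(300, 0.45), random_dna(240, 0.45)))
    cds$length <- nchar(cds$sequence)
  })
  substr(cds$sequence[1], 50, 50) <- "C"
  substr(cds$sequence[2], 30, 30) <- "C"
  ed <- tibble::tibble(gene = c("g1", "g2"), cds_pos = c(50L, 30L),
                       ref_base = "C", edited_base = "T",
                       efficiency = c(1, 0.5))
  sn <- tibble::tibble(gene = "g1", cds_pos = 100L, alt_base = "A")
  substr(cds$sequence[1], 100, 100) <- "G"
  rw <- simulate_rnaseq_wgs(cds, ed, sn, depth = 50L, seed = 5)
  expect_equal(rw$truth$editing$n_edited[1], 50L)   # efficiency 1: all reads
  expect_equal(rw$truth$editing$n_edited[2], 25L)   # exact-count model
  # pileups recover edits, and the SNP appears in both read sets
  org <- c(g1 = "mito", g2 = "mito")
  rp <- pileup_cds(rw$rna_reads, cds)
  wp <- pileup_cds(rw$wgs_reads, cds)
  expect_equal(rp$T[rp$gene == "g1" & rp$cds_pos == 50], 50L)
  expect_equal(rp$T[rp$gene == "g2" & rp$cds_pos == 30], 25L)
  expect_equal(wp$T[wp$gene == "g1" & wp$cds_pos == 50], 0L)
  expect_equal(wp$A[wp$gene == "g1" & wp$cds_pos == 100], 50L)
  expect_equal(rp$A[rp$gene == "g1" & rp$cds_pos == 100], 50L)
})

test_that("binomial efficiency model has binomial spread", {
  withr::with_seed(93, {
    cds <- tibble::tibble(gene = "g1", molecule = "mt1", organelle = "mito",
                          strand = "+", sequence = random_dna(300, 0.45))
    cds$length <- 300L
  })
  substr(cds$sequence, 150, 150) <- "C"
  ed <- tibble::tibble(gene = "g1", cds_pos = 150L, ref_base = "C",
                       edited_base = "T", efficiency = 0.5)
  rw <- simulate_rnaseq_wgs(cds, ed, NULL, depth = 200L,
                            efficiency_model = "binomial", seed = 6)
  n_ed <- rw$truth$editing$n_edited
  expect_lt(abs(n_ed - 100), 3 * sqrt(200 * 0.25))
})

test_that("invalid editing specs are rejected", {
  cds <- tibble::tibble(gene = "g1", molecule = "mt1", organelle = "mito",
                        strand = "+", sequence = strrep("ACG", 50),
                        length = 150L)
  bad_gene <- tibble::tibble(gene = "nope", cds_pos = 5L, ref_base = "C",
                             edited_base = "T", efficiency = 0.5)
  expect_error(simulate_rnaseq_wgs(cds, bad_gene), "outside any PCG")
  bad_pos <- tibble::tibble(gene = "g1", cds_pos = 500L, ref_base = "C",
                            edited_base = "T", efficiency = 0.5)
  expect_error(simulate_rnaseq_wgs(cds, bad_pos), "position")
})

test_that("unplaceable specs fail with an informative error", {
  cfg <- small_config(15)
  cfg$repeat_specs <- tibble::tibble(length = rep(9000L, 5),
                                     orientation = "direct",
                                     placement = "intra")
  expect_error(simulate_genomes(cfg), "could not place")
})
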