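make_direct_toy <- function(seed = 21, flank = 200L, rep_len = 120L,
                            big = FALSE) {
  withr::with_seed(seed, {
    k <- if (big) 3L else 1L
    U <- random_dna(1000 * k, 0.45); V <- random_dna(1500 * k, 0.45)
    W <- random_dna(1000 * k, 0.45); X <- random_dna(900 * k, 0.45)
    R <- random_dna(rep_len, 0.45)
    s <- paste0(U, R, V, W, R, X)
    a1 <- nchar(U) + 1L
    list(mol = molecule_table("m1", s), R = R, U = U, V = V, W = W, X = X,
         rp = tibble::tibble(
           repeat_id = "R1", molecule1 = "m1", start1 = a1,
           end1 = a1 + rep_len - 1L, molecule2 = "m1",
           start2 = nchar(U) + rep_len + nchar(V) + nchar(W) + 1L,
           end2 = nchar(U) + 2L * rep_len + nchar(V) + nchar(W),
           orientation = "direct"))
  })
}

test_that("crossover paths of a direct repeat exchange the flanks", {
  toy <- make_direct_toy(flank = 200L)
  cs <- build_conformations(toy$mol, toy$rp, flank = 200L)
  last <- function(x, k) substr(x, nchar(x) - k + 1L, nchar(x))
  expect_equal(cs$paths$m1, paste0(last(toy$U, 200), toy$R,
                                   substr(toy$V, 1, 200)))
  expect_equal(cs$paths$m2, paste0(last(toy$W, 200), toy$R,
                                   substr(toy$X, 1, 200)))
  expect_equal(cs$paths$s1, paste0(last(toy$U, 200), toy$R,
                                   substr(toy$X, 1, 200)))
  expect_equal(cs$paths$s2, paste0(last(toy$W, 200), toy$R,
                                   substr(toy$V, 1, 200)))
  expect_false(cs$truncated)
  # m-paths are substrings of the genome, s-paths are not
  s <- toy$mol$sequence
  expect_true(grepl(cs$paths$m1, s, fixed = TRUE))
  expect_true(grepl(cs$paths$m2, s, fixed = TRUE))
  expect_false(grepl(cs$paths$s1, s, fixed = TRUE))
  expect_false(grepl(cs$paths$s2, s, fixed = TRUE))
})

test_that("inverted-repeat crossover paths occur in the enumerated
           inversion product", {
  withr::with_seed(22, {
    U <- random_dna(1200, 0.45); M <- random_dna(2500, 0.45)
    X <- random_dna(1100, 0.45); R <- random_dna(150, 0.45)
    s <- paste0(U, R, M, revcomp(R), X)
    mol <- molecule_table("m1", s)
  })
  a1 <- nchar(U) + 1L
  a2 <- nchar(U) + 150L + nchar(M) + 1L
  rp <- tibble::tibble(repeat_id = "R1", molecule1 = "m1", start1 = a1,
                       end1 = a1 + 149L, molecule2 = "m1", start2 = a2,
                       end2 = a2 + 149L, orientation = "inverted")
  cs <- build_conformations(mol, rp, flank = 300L)
  # recombination between inverted copies inverts the intervening segment
  product <- paste0(U, R, revcomp(M), revcomp(R), X)
  hay <- c(product, revcomp(product))
  for (p in c("s1", "s2")) {
    expect_true(any(vapply(hay, grepl, logical(1), pattern = cs$paths[[p]],
                           fixed = TRUE)),
                info = paste("path", p, "not a crossover-product substring"))
  }
  # and the m-paths occur in the original, not in the product
  expect_true(grepl(cs$paths$m1, s, fixed = TRUE))
  expect_true(any(vapply(c(s, revcomp(s)), grepl, logical(1),
                         pattern = cs$paths$m2, fixed = TRUE)))
  expect_false(grepl(cs$paths$s1, s, fixed = TRUE))
})

test_that("circular topology supplies wrap-around flanks", {
  withr::with_seed(23, {
    n <- 9000L
    s <- chars_(random_dna(n, 0.45))
    R <- random_dna(200, 0.45)
    s[8801:9000] <- chars_(R)      # copy 1 ends exactly at the origin
    s[4001:4200] <- chars_(R)
    mol <- molecule_table("m1", paste(s, collapse = ""),
                          topology = "circular")
  })
  rp <- tibble::tibble(repeat_id = "R1", molecule1 = "m1", start1 = 8801L,
                       end1 = 9000L, molecule2 = "m1", start2 = 4001L,
                       end2 = 4200L, orientation = "direct")
  # flanks must wrap with no gap: downstream of copy 1 is the genome start
  cs <- build_conformations(mol, rp, flank = 500L)
  expect_false(cs$truncated)
  seqstr <- mol$sequence
  expect_equal(nchar(cs$paths$m1), 500L + 200L + 500L)
  expect_equal(substr(cs$paths$m1, 701, 1200), substr(seqstr, 1, 500))
  lin <- molecule_table("m1", seqstr, topology = "linear")
  expect_warning(cs2 <- build_conformations(lin, rp, flank = 500L), NA)
  expect_true(cs2$truncated)
})

test_that("spanning classification labels perfect and truncated reads", {
  toy <- make_direct_toy(flank = 1000L, rep_len = 150L)
  cs <- build_conformations(toy$mol, toy$rp, flank = 500L)
  reads <- tibble::tibble(
    read_id = c("exact_m1", "exact_s1_rc", "short_flank", "unrelated"),
    sequence = c(cs$paths$m1,
                 revcomp(cs$paths$s1),
                 substr(cs$paths$m1, 301, nchar(cs$paths$m1)),  # 200bp flank
                 random_dna(1200, 0.5)))
  calls <- classify_spanning_reads(reads, cs)
  expect_equal(calls$label,
               c("major", "alternative", "none", "none"))
  expect_equal(calls$best_path[1:2], c("m1", "s1"))
  expect_equal(calls$identity[1:2], c(1, 1))
  expect_true(all(calls$spans[1:2]))
  expect_false(any(calls$spans[3:4]))
})

test_that("noisy crossover reads are recovered as alternative", {
  toy <- make_direct_toy(seed = 31, flank = 1000L, rep_len = 200L,
                         big = TRUE)
  cs <- build_conformations(toy$mol, toy$rp, flank = 1000L)
  sim <- simulate_spanning_reads(toy$mol, toy$rp, n = 60, alt_fraction = 1,
                                 flank = 1000L, sub_rate = 0.05,
                                 ins_rate = 0.015, del_rate = 0.015,
                                 seed = 7)
  calls <- classify_spanning_reads(sim$reads, cs)
  expect_gte(mean(calls$label == "alternative"), 0.99)
  expect_equal(sum(calls$label == "major"), 0L)
})

test_that("support counting applies the max-of-same-conformation rule", {
  calls <- tibble::tibble(
    read_id = sprintf("r%02d", 1:10),
    repeat_id = "LR11",
    label = c(rep("major", 5), rep("alternative", 3), "ambiguous", "none"),
    best_path = c("m1", "m1", "m1", "m2", "m2", "s1", "s2", "s2",
                  "none", "none"),
    identity = 0.99, spans = c(rep(TRUE, 9), FALSE))
  q <- quantify_recombination(calls)
  expect_equal(q$n_major, 3L)          # max(3 m1, 2 m2)
  expect_equal(q$n_alternative, 2L)    # max(1 s1, 2 s2)
  expect_equal(q$n_ambiguous, 1L)
  expect_equal(q$pct_major, 60)
  expect_equal(q$pct_alternative, 40)
  expect_true(q$active)
})

test_that("support percentages reproduce printed-count arithmetic", {
  p <- recombination_percentages(c(41, 189, 12), c(18, 0, 13))
  expect_equal(p$pct_major, c(69.49, 100.00, 48.00))
  expect_equal(p$pct_alternative, c(30.51, 0.00, 52.00))
  # closure within rounding
  expect_true(all(abs(p$pct_major + p$pct_alternative - 100) <= 0.01))
  empty <- recombination_percentages(0, 0)
  expect_true(is.na(empty$pct_major))
})

test_that("MTPT integration verification needs mitochondrial context", {
  withr::with_seed(41, {
    mt <- chars_(random_dna(12000, 0.45))
    cp_seg <- random_dna(800, 0.38)
    mt[5001:5800] <- chars_(cp_seg)
    mols <- molecule_table(c("mt1", "cp"),
                           c(paste(mt, collapse = ""),
                             paste0(random_dna(2000, 0.38), cp_seg,
                                    random_dna(2000, 0.38))),
                           organelle = c("mito", "plastid"))
  })
  spanning <- tibble::tibble(
    read_id = "good",
    sequence = substr(mols$sequence[1], 4000, 6800))
  v <- verify_mtpt_integration(spanning, mols, "mt1", 5001L, 5800L,
                               flank = 800L)
  expect_true(v$verified)
  expect_equal(v$n_supporting, 1L)
  # reads from the plastid only: the segment without mt flanks
  cp_read <- tibble::tibble(
    read_id = "cp_only",
    sequence = substr(mols$sequence[2], 1500, 5300))
  v2 <- verify_mtpt_integration(cp_read, mols, "mt1", 5001L, 5800L,
                                flank = 800L)
  expect_false(v2$verified)
  expect_equal(v2$n_supporting, 0L)
})
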