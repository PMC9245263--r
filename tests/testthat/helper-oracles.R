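# Independent oracles used across the suite. These deliberately share no
# code with the package's search/alignment paths.

chars_ <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

# All maximal repeated pairs of a single linear sequence by full
# longest-common-extension dynamic programming. Direct and inverted.
brute_repeats <- function(s, min_len, id = "m") {
  v <- chars_(s)
  n <- length(v)
  lce <- function(a, b) {
    # M[i, j] = length of the longest common extension of a[i..], b[j..]
    na <- length(a); nb <- length(b)
    M <- matrix(0L, na + 1L, nb + 1L)
    for (i in na:1) {
      M[i, 1:nb] <- ifelse(a[i] == b, 1L + M[i + 1L, 2:(nb + 1L)], 0L)
    }
    M
  }
  collect <- function(M, a, b) {
    idx <- which(M[seq_along(a), seq_along(b), drop = FALSE] >= min_len,
                 arr.ind = TRUE)
    if (nrow(idx) == 0) return(NULL)
    i <- idx[, 1]; j <- idx[, 2]
    left_max <- i == 1L | j == 1L |
      a[pmax(i - 1L, 1L)] != b[pmax(j - 1L, 1L)]
    i <- i[left_max]; j <- j[left_max]
    if (length(i) == 0) return(NULL)
    L <- M[cbind(i, j)]
    tibble::tibble(i = i, j = j, len = L)
  }
  out <- list()
  # direct
  M <- lce(v, v)
  d <- collect(M, v, v)
  if (!is.null(d)) {
    d <- d[d$j > d$i, , drop = FALSE]
    if (nrow(d) > 0) {
      out$fwd <- tibble::tibble(
        molecule1 = id, start1 = d$i, end1 = d$i + d$len - 1L,
        molecule2 = id, start2 = d$j, end2 = d$j + d$len - 1L,
        orientation = "forward", length = d$len)
    }
  }
  # inverted: compare with the reverse complement
  w <- chars_(paste(rev(chartr("ACGT", "TGCA", v)), collapse = ""))
  M <- lce(v, w)
  d <- collect(M, v, w)
  if (!is.null(d) && nrow(d) > 0) {
    s2 <- n - (d$j + d$len - 1L) + 1L
    e2 <- n - d$j + 1L
    r <- tibble::tibble(
      molecule1 = id, start1 = d$i, end1 = d$i + d$len - 1L,
      molecule2 = id, start2 = s2, end2 = e2,
      orientation = "reverse", length = d$len)
    swap <- r$start2 < r$start1
    if (any(swap)) {
      tmp <- r[swap, ]
      r[swap, c("start1", "end1")] <- tmp[, c("start2", "end2")]
      r[swap, c("start2", "end2")] <- tmp[, c("start1", "end1")]
    }
    out$rev <- dplyr::distinct(r)
  }
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0) {
    return(tibble::tibble(molecule1 = character(), start1 = integer(),
                          end1 = integer(), molecule2 = character(),
                          start2 = integer(), end2 = integer(),
                          orientation = character(), length = integer()))
  }
  dplyr::arrange(res, dplyr::desc(length), start1, start2, orientation)
}

# Smith-Waterman optimum via Biostrings (full dynamic programme), same
# +2/-3 substitution scores and 5 + 2k gap cost.
sw_oracle_score <- function(a, b) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3,
                                                  baseOnly = TRUE)
  al <- Biostrings::pairwiseAlignment(a, b, type = "local",
                                      substitutionMatrix = mat,
                                      gapOpening = 5, gapExtension = 2)
  Biostrings::score(al)
}

# union of 1-based inclusive intervals by per-base boolean marking
union_bp_oracle <- function(starts, ends, n) {
  marked <- logical(n)
  for (k in seq_along(starts)) {
    marked[seq.int(min(starts[k], ends[k]), max(starts[k], ends[k]))] <- TRUE
  }
  sum(marked)
}

# random sequence with planted repeat structure for oracle comparisons
make_repeat_instance <- function(seed, n = 1600, min_len = 25) {
  withr::with_seed(seed, {
    s <- chars_(random_dna(n, 0.45))
    seg <- random_dna(80, 0.45)
    short <- random_dna(30, 0.45)
    slots <- cumsum(c(sample(50:120, 1),
                      sample(180:280, 4, replace = TRUE)))
    stopifnot(max(slots) + 100 <= n)
    s[slots[1]:(slots[1] + 79)] <- chars_(seg)
    s[slots[2]:(slots[2] + 79)] <- chars_(seg)
    s[slots[3]:(slots[3] + 79)] <- chars_(revcomp(seg))
    s[slots[4]:(slots[4] + 29)] <- chars_(short)
    s[slots[5]:(slots[5] + 29)] <- chars_(short)
    paste(s, collapse = "")
  })
}

# sequence pair with a planted homologous core for aligner oracle tests;
# the core keeps an exact >= 15 bp centre so a word-9 seed always exists
make_homology_pair <- function(seed, max_len = 300) {
  withr::with_seed(seed, {
    core_len <- sample(60:140, 1)
    core <- random_dna(core_len, 0.5)
    mutated <- chars_(core)
    n_mut <- sample(0:6, 1)
    centre <- (core_len %/% 2 - 7):(core_len %/% 2 + 8)
    cand <- setdiff(seq_len(core_len), centre)
    if (n_mut > 0) {
      pos <- sample(cand, n_mut)
      for (p in pos) {
        mutated[p] <- sample(setdiff(c("A", "C", "G", "T"), mutated[p]), 1)
      }
    }
    # up to 2 single-base indels outside the centre
    n_ind <- sample(0:2, 1)
    if (n_ind > 0) {
      for (p in sort(sample(setdiff(cand, if (n_mut > 0) pos else NULL),
                            n_ind), decreasing = TRUE)) {
        if (runif(1) < 0.5) mutated <- mutated[-p]
        else mutated <- append(mutated, sample(c("A", "C", "G", "T"), 1), p)
      }
    }
    fl <- function(k) random_dna(k, 0.5)
    a <- paste0(fl(sample(20:80, 1)), core, fl(sample(20:80, 1)))
    b <- paste0(fl(sample(20:80, 1)), paste(mutated, collapse = ""),
                fl(sample(20:80, 1)))
    stopifnot(nchar(a) <= max_len, nchar(b) <= max_len)
    list(a = a, b = b)
  })
}
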