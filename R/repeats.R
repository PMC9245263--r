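# exact seed matches between x and y: tibble(i, j) of start positions whose
# k-mers agree; self = TRUE restricts to j > i (same sequence, same strand)
seed_pairs <- function(x, y, k, self = FALSE) {
  nx <- nchar(x); ny <- nchar(y)
  if (nx < k || ny < k) return(tibble(i = integer(), j = integer()))
  px <- seq_len(nx - k + 1L)
  py <- seq_len(ny - k + 1L)
  kx <- substring(x, px, px + k - 1L)
  ky <- substring(y, py, py + k - 1L)
  ix <- split(px, kx)
  iy <- split(py, ky)
  common <- intersect(names(ix), names(iy))
  if (length(common) == 0) return(tibble(i = integer(), j = integer()))
  out <- lapply(common, function(m) {
    a <- ix[[m]]; b <- iy[[m]]
    if (length(a) * length(b) > 50000) return(NULL)   # low-complexity guard
    g <- expand.grid(i = a, j = b)
    g
  })
  out <- dplyr::bind_rows(out)
  if (self && nrow(out) > 0) out <- out[out$j > out$i, , drop = FALSE]
  as_tibble(out)
}

# merge seeds on a common diagonal into maximal runs, then extend by direct
# character comparison; returns tibble(s1, e1, s2, e2) in x/y coordinates
maximal_runs <- function(seeds, x, y, k, min_len) {
  if (nrow(seeds) == 0) {
    return(tibble(s1 = integer(), e1 = integer(),
                  s2 = integer(), e2 = integer()))
  }
  nx <- nchar(x); ny <- nchar(y)
  seeds$d <- seeds$j - seeds$i
  out <- list()
  for (d in unique(seeds$d)) {
    ii <- sort(seeds$i[seeds$d == d])
    brk <- c(0L, which(diff(ii) > 1L), length(ii))
    for (r in seq_len(length(brk) - 1L)) {
      i0 <- ii[brk[r] + 1L]
      i1 <- ii[brk[r + 1L]]
      s1 <- i0; e1 <- i1 + k - 1L
      s2 <- i0 + d; e2 <- i1 + d + k - 1L
      while (s1 > 1L && s2 > 1L &&
             substr(x, s1 - 1L, s1 - 1L) == substr(y, s2 - 1L, s2 - 1L)) {
        s1 <- s1 - 1L; s2 <- s2 - 1L
      }
      while (e1 < nx && e2 < ny &&
             substr(x, e1 + 1L, e1 + 1L) == substr(y, e2 + 1L, e2 + 1L)) {
        e1 <- e1 + 1L; e2 <- e2 + 1L
      }
      if (e1 - s1 + 1L >= min_len) {
        out[[length(out) + 1L]] <- tibble(s1 = s1, e1 = e1, s2 = s2, e2 = e2)
      }
    }
  }
  if (length(out) == 0) {
    return(tibble(s1 = integer(), e1 = integer(),
                  s2 = integer(), e2 = integer()))
  }
  dplyr::distinct(dplyr::bind_rows(out))
}

#' Find repeat pairs in genome molecules
#'
#' Discovers maximal repeated pairs of at least `min_len` bp: direct and
#' inverted, within one molecule and across molecules. Exact mode (the
#' default) anchors on shared k-mers, merges co-diagonal seed runs and
#' extends them maximally, so reported pairs have identity 1 and nested
#' sub-pairs of a maximal pair are never reported. Circular molecules are
#' searched across the origin by doubling the sequence and discarding
#' hits that lie entirely in the second copy; an interval that crosses
#' the origin is reported with `end > length` (its `wraps` flag set).
#'
#' Near-exact mode (`identity >= min_identity` via the local aligner) is
#' available for diverged repeats but is not the default.
#'
#' @param molecules molecule tibble.
#' @param min_len minimal repeat length (bp, >= 20).
#' @param mode `"exact"` or `"near-exact"`.
#' @param min_identity identity floor for near-exact mode.
#' @return tibble with columns `molecule1`, `start1`, `end1`, `molecule2`,
#'   `start2`, `end2`, `orientation` (`"forward"`/`"reverse"` for copy 2),
#'   `length`, `identity`, `wraps`.
#' @export
find_repeats <- function(molecules, min_len = 100L,
                         mode = c("exact", "near-exact"),
                         min_identity = 0.9) {
  mode <- match.arg(mode)
  if (nrow(molecules) == 0) stop("empty molecule list")
  stopifnot(min_len >= 20)
  if (mode == "near-exact") {
    return(find_repeats_near(molecules, min_len, min_identity))
  }
  k <- min(21L, as.integer(min_len))
  hits <- list()
  mols <- molecules[molecules$organelle == "mito", , drop = FALSE]
  if (nrow(mols) == 0) mols <- molecules
  for (a in seq_len(nrow(mols))) for (b in a:nrow(mols)) {
    na <- mols$length[a]; nb <- mols$length[b]
    xa <- if (mols$topology[a] == "circular")
      paste0(mols$sequence[a], mols$sequence[a]) else mols$sequence[a]
    xb <- if (mols$topology[b] == "circular")
      paste0(mols$sequence[b], mols$sequence[b]) else mols$sequence[b]
    same <- a == b
    # direct
    sp <- seed_pairs(xa, xb, k, self = same)
    runs <- maximal_runs(sp, xa, xb, k, min_len)
    if (nrow(runs) > 0) {
      runs$orientation <- "forward"
      runs$ms1 <- mols$id[a]; runs$ms2 <- mols$id[b]
      hits[[length(hits) + 1L]] <- runs
    }
    # inverted: compare xa against revcomp(xb)
    yb <- revcomp(xb)
    sp <- seed_pairs(xa, yb, k, self = FALSE)
    runs <- maximal_runs(sp, xa, yb, k, min_len)
    if (nrow(runs) > 0) {
      nbe <- nchar(xb)
      s2 <- nbe - runs$e2 + 1L
      e2 <- nbe - runs$s2 + 1L
      runs$s2 <- s2; runs$e2 <- e2
      runs$orientation <- "reverse"
      runs$ms1 <- mols$id[a]; runs$ms2 <- mols$id[b]
      hits[[length(hits) + 1L]] <- runs
    }
  }
  if (length(hits) == 0) {
    return(tibble(molecule1 = character(), start1 = integer(),
                  end1 = integer(), molecule2 = character(),
                  start2 = integer(), end2 = integer(),
                  orientation = character(), length = integer(),
                  identity = numeric(), wraps = logical()))
  }
  h <- dplyr::bind_rows(hits)
  # map doubled-circle coordinates back to the original molecule
  topo <- setNames(mols$topology, mols$id)
  lens <- setNames(mols$length, mols$id)
  fix <- function(s, e, mol) {
    n <- unname(lens[mol])
    circ <- unname(topo[mol] == "circular")
    shift <- ifelse(circ & s > n, n, 0L)
    list(s = as.integer(s - shift), e = as.integer(e - shift))
  }
  c1 <- fix(h$s1, h$e1, h$ms1)
  c2 <- fix(h$s2, h$e2, h$ms2)
  h$s1 <- c1$s; h$e1 <- c1$e; h$s2 <- c2$s; h$e2 <- c2$e
  h$len <- h$e1 - h$s1 + 1L
  # cap degenerate full-rotation self matches of a doubled circle
  h <- h[h$len <= unname(pmin(lens[h$ms1], lens[h$ms2])), , drop = FALSE]
  # drop artefactual self pairs (a circular copy matching its own double)
  h <- h[!(h$ms1 == h$ms2 & h$s1 == h$s2 & h$e1 == h$e2 &
             h$orientation == "forward"), , drop = FALSE]
  # canonical copy order
  swap <- (h$ms2 < h$ms1) | (h$ms1 == h$ms2 & h$s2 < h$s1)
  if (any(swap)) {
    tmp <- h[swap, ]
    h[swap, c("ms1", "s1", "e1")] <-
      setNames(tmp[, c("ms2", "s2", "e2")], c("ms1", "s1", "e1"))
    h[swap, c("ms2", "s2", "e2")] <-
      setNames(tmp[, c("ms1", "s1", "e1")], c("ms2", "s2", "e2"))
  }
  h <- dplyr::distinct(h, .data$ms1, .data$s1, .data$e1, .data$ms2,
                       .data$s2, .data$e2, .data$orientation,
                       .keep_all = TRUE)
  tibble(molecule1 = h$ms1, start1 = h$s1, end1 = h$e1,
         molecule2 = h$ms2, start2 = h$s2, end2 = h$e2,
         orientation = h$orientation, length = h$len, identity = 1,
         wraps = unname(h$e1 > lens[h$ms1] | h$e2 > lens[h$ms2])) |>
    arrange(desc(.data$length), .data$molecule1, .data$start1,
            .data$molecule2, .data$start2)
}

# near-exact repeats through the seed-and-extend local aligner
find_repeats_near <- function(molecules, min_len, min_identity) {
  mols <- molecules[molecules$organelle == "mito", , drop = FALSE]
  if (nrow(mols) == 0) mols <- molecules
  params <- alignment_params(evalue_max = 1e-5)
  out <- list()
  for (a in seq_len(nrow(mols))) for (b in a:nrow(mols)) {
    al <- local_align(mols$sequence[a], mols$sequence[b], params)
    if (nrow(al) == 0) next
    al <- al[al$identity >= min_identity &
               pmin(al$q_end - al$q_start, abs(al$s_end - al$s_start)) + 1 >=
               min_len, , drop = FALSE]
    if (a == b && nrow(al) > 0) {
      al <- al[!(al$q_start == pmin(al$s_start, al$s_end) &
                   al$strand == "+"), , drop = FALSE]
      al <- al[al$q_start < pmin(al$s_start, al$s_end), , drop = FALSE]
    }
    if (nrow(al) == 0) next
    out[[length(out) + 1L]] <- tibble(
      molecule1 = mols$id[a], start1 = al$q_start, end1 = al$q_end,
      molecule2 = mols$id[b],
      start2 = pmin(al$s_start, al$s_end),
      end2 = pmax(al$s_start, al$s_end),
      orientation = ifelse(al$strand == "+", "forward", "reverse"),
      length = al$q_end - al$q_start + 1L, identity = al$identity,
      wraps = FALSE)
  }
  if (length(out) == 0) {
    return(tibble(molecule1 = character(), start1 = integer(),
                  end1 = integer(), molecule2 = character(),
                  start2 = integer(), end2 = integer(),
                  orientation = character(), length = integer(),
                  identity = numeric(), wraps = logical()))
  }
  dplyr::bind_rows(out) |>
    arrange(desc(.data$length), .data$molecule1, .data$start1)
}

#' Classify repeats as long or short and assign ids
#'
#' Pairs at or above `long_threshold` get the `LR` prefix, the rest `SR`;
#' within each class ids run by descending length, ties broken by
#' (molecule, start) of the first copy.
#'
#' @param pairs tibble from [find_repeats()].
#' @param long_threshold length threshold in bp.
#' @return the input with `klass` and `repeat_id` columns prepended.
#' @export
classify_repeats <- function(pairs, long_threshold = 1000L) {
  stopifnot(nrow(pairs) > 0)
  pairs <- pairs |>
    mutate(klass = ifelse(.data$length >= long_threshold, "long", "short")) |>
    arrange(desc(.data$length), .data$molecule1, .data$start1,
            .data$molecule2, .data$start2) |>
    group_by(.data$klass) |>
    mutate(repeat_id = paste0(ifelse(.data$klass == "long", "LR", "SR"),
                              row_number())) |>
    ungroup()
  select(pairs, "repeat_id", "klass", dplyr::everything())
}

#' Write a repeat table in location-column format
#'
#' Emits a TSV with 1-based inclusive coordinates where reverse-oriented
#' second copies carry descending coordinates.
#'
#' @param pairs classified repeat tibble.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_repeat_table <- function(pairs, path) {
  cc <- coords_to_table(pairs$start2, pairs$end2,
                        ifelse(pairs$orientation == "reverse", "-", "+"))
  out <- tibble(id = pairs$repeat_id, length = pairs$length,
                molecule1 = pairs$molecule1, start1 = pairs$start1,
                end1 = pairs$end1, molecule2 = pairs$molecule2,
                start2 = cc$start, end2 = cc$end,
                orientation = pairs$orientation, identity = pairs$identity)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
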