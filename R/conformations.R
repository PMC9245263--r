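#' Build the four local conformations around a repeat
#'
#' For a repeat with copies A and B, the two major paths reproduce the
#' reference: `m1 = A_up R A_down`, `m2 = B_up R B_down`; the two
#' crossover (secondary) paths exchange flanks: `s1 = A_up R B_down`,
#' `s2 = B_up R A_down`. For an inverted copy B its flanks enter the
#' paths reverse-complemented, so every path is a valid linear DNA
#' sequence. Each flank is extended `flank` bp (default 1 kb) so that
#' mapped long reads can be required to span the repeat completely;
#' circular molecules supply wrap-around flanks, and a flank truncated by
#' the end of a linear molecule is recorded in the provenance.
#'
#' @param molecules molecule tibble.
#' @param rp one-row repeat tibble (`molecule1`, `start1`, `end1`,
#'   `molecule2`, `start2`, `end2`, `orientation`).
#' @param flank flank length in bp.
#' @return an object of class `conformation_set`: list with `repeat_id`,
#'   `flank`, `paths` (named list m1, m2, s1, s2), `provenance` tibble,
#'   and `truncated` flag.
#' @export
build_conformations <- function(molecules, rp, flank = 1000L) {
  rp <- as.list(rp[1, , drop = FALSE])
  m1 <- molecules[molecules$id == rp$molecule1, ]
  m2 <- molecules[molecules$id == rp$molecule2, ]
  if (nrow(m1) != 1 || nrow(m2) != 1) stop("repeat molecules not found")
  if (rp$end1 > m1$length + m1$length || rp$end2 > 2 * m2$length ||
      rp$start1 < 1 || rp$start2 < 1) {
    stop("repeat coordinates outside molecule bounds")
  }
  if (rp$molecule1 == rp$molecule2 &&
      min(abs(rp$start2 - rp$end1), abs(rp$start1 - rp$end2)) < 2 * flank) {
    warning("repeat copies closer than 2 x flank; crossover paths overlap ",
            "the opposite copy")
  }
  R <- as.character(mol_substr(m1$sequence, rp$start1, rp$end1, m1$topology))

  take <- function(mol, s, e) {
    x <- mol_substr(mol$sequence, s, e, mol$topology)
    list(seq = as.character(x), truncated = isTRUE(attr(x, "truncated")),
         start = s, end = e)
  }
  a_up <- take(m1, rp$start1 - flank, rp$start1 - 1L)
  a_dn <- take(m1, rp$end1 + 1L, rp$end1 + flank)
  if (rp$orientation == "direct" || rp$orientation == "forward") {
    b_up <- take(m2, rp$start2 - flank, rp$start2 - 1L)
    b_dn <- take(m2, rp$end2 + 1L, rp$end2 + flank)
  } else {
    raw_up <- take(m2, rp$end2 + 1L, rp$end2 + flank)
    raw_dn <- take(m2, rp$start2 - flank, rp$start2 - 1L)
    b_up <- list(seq = revcomp(raw_up$seq), truncated = raw_up$truncated,
                 start = raw_up$start, end = raw_up$end)
    b_dn <- list(seq = revcomp(raw_dn$seq), truncated = raw_dn$truncated,
                 start = raw_dn$start, end = raw_dn$end)
  }
  paths <- list(
    m1 = paste0(a_up$seq, R, a_dn$seq),
    m2 = paste0(b_up$seq, R, b_dn$seq),
    s1 = paste0(a_up$seq, R, b_dn$seq),
    s2 = paste0(b_up$seq, R, a_dn$seq))
  prov <- tibble(
    flank_id = c("A_up", "A_down", "B_up", "B_down"),
    molecule = c(rp$molecule1, rp$molecule1, rp$molecule2, rp$molecule2),
    start = c(a_up$start, a_dn$start, b_up$start, b_dn$start),
    end = c(a_up$end, a_dn$end, b_up$end, b_dn$end),
    truncated = c(a_up$truncated, a_dn$truncated, b_up$truncated,
                  b_dn$truncated))
  structure(list(
    repeat_id = if (!is.null(rp$repeat_id)) rp$repeat_id else "R",
    flank = flank, repeat_length = nchar(R), paths = paths,
    provenance = prov, truncated = any(prov$truncated)),
    class = "conformation_set")
}

#' @export
print.conformation_set <- function(x, ...) {
  cat("<conformation_set>", x$repeat_id, "repeat", x$repeat_length,
      "bp, flank", x$flank, "bp\n")
  cat("  path lengths:",
      paste(names(x$paths), vapply(x$paths, nchar, 1L), collapse = " "), "\n")
  if (x$truncated) cat("  note: flank(s) truncated at a molecule end\n")
  invisible(x)
}

#' Classify long reads against the four conformations of a repeat
#'
#' Each read (or its reverse complement, whichever anchors better) is
#' aligned to every conformation path with a k-mer-anchored banded
#' alignment in which the path is aligned end to end and the read's
#' overhangs are free. A path is *supported* only when the alignment
#' covers the full repeat plus both full flanks (no terminal path
#' clipping) at identity >= `min_identity`. Reads supporting only major
#' paths are labelled `major`, only crossover paths `alternative`; reads
#' supporting both classes within `ambiguity_margin` identity are
#' `ambiguous`, mirroring manual curation of undecidable reads; all
#' others are `none`.
#'
#' @param reads read tibble (`read_id`, `sequence`).
#' @param cs a [build_conformations()] object.
#' @param min_identity spanning-acceptance identity threshold.
#' @param ambiguity_margin identity difference below which a read
#'   supporting both classes is ambiguous.
#' @param band band half-width for the alignment; default scales with
#'   path length.
#' @return tibble with `read_id`, `repeat_id`, `label`, `best_path`,
#'   `identity`, `spans`.
#' @export
classify_spanning_reads <- function(reads, cs, min_identity = 0.85,
                                    ambiguity_margin = 0.02, band = NULL) {
  stopifnot(inherits(cs, "conformation_set"))
  paths <- cs$paths
  path_names <- names(paths)
  plen <- nchar(paths$m1)
  # band absorbs anchoring error (<= 16), indel drift (~3% of the path)
  # and a safety floor
  if (is.null(band)) band <- max(64L, as.integer(ceiling(0.025 * plen)) + 24L)
  n <- nrow(reads)
  label <- rep("none", n)
  best_path <- rep("none", n)
  identity <- rep(NA_real_, n)
  spans <- rep(FALSE, n)
  for (i in seq_len(n)) {
    s <- reads$sequence[i]
    if (nchar(s) == 0) stop("read of length 0: ", reads$read_id[i])
    rc <- revcomp(s)
    vf <- cpp_diag_vote(paths$m1, s, 13L, 8L)
    vr <- cpp_diag_vote(paths$m1, rc, 13L, 8L)
    use <- if (vr$votes > vf$votes) rc else s
    ids <- rep(NA_real_, 4L)
    for (p in 1:4) {
      v <- cpp_diag_vote(paths[[p]], use, 13L, 8L)
      if (v$votes < 2) next
      al <- cpp_glocal_band(paths[[p]], use, v$offset, band, 2L, -3L, 5L, 2L)
      if (is.na(al$score[1]) || al$left_del > 0 || al$right_del > 0) next
      cols <- al$n_match + al$n_mismatch + al$n_del + al$n_ins
      ids[p] <- al$n_match / cols
    }
    sup <- which(!is.na(ids) & ids >= min_identity)
    if (length(sup) == 0) next
    best_m <- suppressWarnings(max(ids[intersect(sup, 1:2)]))
    best_s <- suppressWarnings(max(ids[intersect(sup, 3:4)]))
    both <- is.finite(best_m) && is.finite(best_s)
    spans[i] <- TRUE
    if (both && abs(best_m - best_s) < ambiguity_margin) {
      label[i] <- "ambiguous"
      identity[i] <- max(best_m, best_s)
    } else {
      cls <- if (!is.finite(best_s) || (both && best_m > best_s)) 1:2 else 3:4
      pick <- intersect(sup, cls)
      pick <- pick[which.max(ids[pick])]
      label[i] <- if (pick <= 2) "major" else "alternative"
      best_path[i] <- path_names[pick]
      identity[i] <- ids[pick]
    }
  }
  tibble(read_id = reads$read_id, repeat_id = cs$repeat_id, label = label,
         best_path = best_path, identity = identity, spans = spans)
}

#' Percentage arithmetic for conformation support counts
#'
#' `pct = 100 * n / (n_major + n_alternative)`, rounded half-up to two
#' decimals; both percentages are `NA` when no read supports either
#' conformation.
#'
#' @param n_major,n_alternative supporting read counts.
#' @return tibble with `pct_major`, `pct_alternative`.
#' @export
recombination_percentages <- function(n_major, n_alternative) {
  tot <- n_major + n_alternative
  tibble(
    pct_major = ifelse(tot > 0, round_half_up(100 * n_major / tot, 2),
                       NA_real_),
    pct_alternative = ifelse(tot > 0,
                             round_half_up(100 * n_alternative / tot, 2),
                             NA_real_))
}

#' Quantify recombination support for one repeat
#'
#' Aggregates per-read calls: of the two paths supporting the same
#' conformation only the one with the larger read count is counted
#' (`n_major = max(#m1, #m2)`, `n_alternative = max(#s1, #s2)`);
#' ambiguous reads are excluded from both counts and from the
#' percentage denominator. A repeat is recombinationally `active` when
#' at least one read supports a crossover path.
#'
#' @param calls tibble from [classify_spanning_reads()].
#' @param repeat_id optional repeat id filter / label.
#' @return one-row tibble of class `recomb_support` with `repeat_id`,
#'   `n_major`, `n_alternative`, `n_ambiguous`, `pct_major`,
#'   `pct_alternative`, `active`.
#' @export
quantify_recombination <- function(calls, repeat_id = NULL) {
  if (is.null(repeat_id)) {
    repeat_id <- unique(calls$repeat_id)
    if (length(repeat_id) != 1) stop("calls span several repeats; pass one")
  } else {
    calls <- calls[calls$repeat_id == repeat_id, , drop = FALSE]
  }
  cnt <- function(p) sum(calls$best_path == p &
                           calls$label %in% c("major", "alternative"))
  n_major <- max(cnt("m1"), cnt("m2"))
  n_alt <- max(cnt("s1"), cnt("s2"))
  pct <- recombination_percentages(n_major, n_alt)
  out <- tibble(repeat_id = repeat_id, n_major = n_major,
                n_alternative = n_alt,
                n_ambiguous = sum(calls$label == "ambiguous"),
                pct_major = pct$pct_major,
                pct_alternative = pct$pct_alternative,
                active = n_alt > 0)
  class(out) <- c("recomb_support", class(out))
  out
}

#' Verify MTPT integration with spanning long reads
#'
#' A plastid-derived segment is considered integrated into the
#' mitochondrial genome when at least one long read covers the whole
#' segment plus at least `flank` bp of flanking mitochondrial sequence on
#' both sides at identity >= `min_identity`. A segment abutting the end
#' of a linear molecule is checked one-sided and flagged.
#'
#' @param reads read tibble.
#' @param molecules molecule tibble.
#' @param mt_molecule id of the mitochondrial molecule carrying the
#'   segment.
#' @param start,end 1-based inclusive segment interval.
#' @param flank required flanking coverage (bp).
#' @param min_identity acceptance identity.
#' @return list with `verified`, `n_supporting`, `one_sided`.
#' @export
verify_mtpt_integration <- function(reads, molecules, mt_molecule, start,
                                    end, flank = 1000L,
                                    min_identity = 0.85) {
  mol <- molecules[molecules$id == mt_molecule, ]
  if (nrow(mol) != 1) stop("molecule not found: ", mt_molecule)
  if (start < 1 || end > mol$length || start > end) {
    stop("invalid MTPT interval")
  }
  tgt <- mol_substr(mol$sequence, start - flank, end + flank, mol$topology)
  one_sided <- isTRUE(attr(tgt, "truncated"))
  if (one_sided) warning("MTPT abuts a linear molecule end; one-sided check")
  tgt <- as.character(tgt)
  band <- max(50L, as.integer(0.12 * nchar(tgt)))
  n_sup <- 0L
  for (i in seq_len(nrow(reads))) {
    s <- reads$sequence[i]
    rc <- revcomp(s)
    vf <- cpp_diag_vote(tgt, s, 13L, 8L)
    vr <- cpp_diag_vote(tgt, rc, 13L, 8L)
    v <- if (vr$votes > vf$votes) vr else vf
    if (v$votes < 2) next
    use <- if (vr$votes > vf$votes) rc else s
    al <- cpp_glocal_band(tgt, use, v$offset, band, 2L, -3L, 5L, 2L)
    if (is.na(al$score[1])) next
    cols <- al$n_match + al$n_mismatch + al$n_del + al$n_ins
    if (al$left_del == 0 && al$right_del == 0 &&
        al$n_match / cols >= min_identity) {
      n_sup <- n_sup + 1L
    }
  }
  list(verified = n_sup >= 1L, n_supporting = n_sup, one_sided = one_sided)
}
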