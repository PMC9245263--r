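#' BLASTn-style alignment parameters
#'
#' Scoring scheme and thresholds of the seed-and-extend local aligner.
#' Defaults follow the megablast-style nucleotide setup used for
#' organelle homology searches: exact 9-mer seeds, +2/-3
#' match/mismatch, affine gaps costing `gap_open + gap_ext * length`
#' (first gap column included), E-value cutoff 1e-5, no low-complexity
#' masking. `lambda` and `K` are the published gapped Karlin-Altschul
#' parameters for the +2/-3, 5/2 scheme and feed
#' `E = K * m * n * exp(-lambda * S)` with m, n the full sequence
#' lengths.
#'
#' @param word_size exact seed length (>= 4).
#' @param match,mismatch substitution scores.
#' @param gap_open,gap_ext positive gap penalties.
#' @param evalue_max E-value cutoff.
#' @param lambda,K Karlin-Altschul parameters.
#' @param xdrop ungapped extension X-drop.
#' @param min_hsp_score minimal ungapped HSP score sent to the gapped
#'   stage.
#' @param window_pad bp of context around an HSP given to the gapped
#'   stage.
#' @param band gapped-stage band half-width.
#' @param max_hsp maximal HSP candidates per strand.
#' @return a list of class `alignment_params`.
#' @export
alignment_params <- function(word_size = 9L, match = 2L, mismatch = -3L,
                             gap_open = 5L, gap_ext = 2L,
                             evalue_max = 1e-5, lambda = 0.625, K = 0.41,
                             xdrop = 20L, min_hsp_score = 20L,
                             window_pad = 3000L, band = 64L,
                             max_hsp = 100L) {
  stopifnot(word_size >= 4, gap_open > 0, gap_ext > 0, match > 0,
            mismatch < 0)
  structure(list(word_size = as.integer(word_size), match = as.integer(match),
                 mismatch = as.integer(mismatch),
                 gap_open = as.integer(gap_open),
                 gap_ext = as.integer(gap_ext), evalue_max = evalue_max,
                 lambda = lambda, K = K, xdrop = as.integer(xdrop),
                 min_hsp_score = as.integer(min_hsp_score),
                 window_pad = as.integer(window_pad), band = as.integer(band),
                 max_hsp = as.integer(max_hsp)),
            class = "alignment_params")
}

# ungapped HSP candidates between query and (possibly reverse-complemented)
# subject: one representative seed per co-diagonal run, X-drop extended
hsp_candidates <- function(query, subject, params) {
  k <- params$word_size
  seeds <- seed_pairs(query, subject, k)
  if (nrow(seeds) == 0) return(NULL)
  seeds$d <- seeds$j - seeds$i
  reps <- seeds |>
    arrange(.data$d, .data$i) |>
    group_by(.data$d) |>
    mutate(run = cumsum(c(1L, diff(.data$i) > 2L * .env$k))) |>
    group_by(.data$d, .data$run) |>
    summarise(i = .data$i[ceiling(n() / 2)], j = .data$j[ceiling(n() / 2)],
              .groups = "drop")
  hsp <- lapply(seq_len(nrow(reps)), function(r) {
    e <- cpp_ungapped_extend(query, subject, reps$i[r], reps$j[r], k,
                             params$match, params$mismatch, params$xdrop)
    tibble(q_start = e$a_start, q_end = e$a_end, s_start = e$b_start,
           s_end = e$b_end, score = e$score)
  })
  hsp <- dplyr::bind_rows(hsp)
  hsp <- hsp[hsp$score >= params$min_hsp_score, , drop = FALSE]
  if (nrow(hsp) == 0) return(NULL)
  hsp <- dplyr::distinct(hsp) |> arrange(desc(.data$score))
  # greedy containment dedupe
  keep <- rep(TRUE, nrow(hsp))
  for (r in seq_len(nrow(hsp))) {
    if (!keep[r]) next
    if (r < nrow(hsp)) {
      later <- (r + 1):nrow(hsp)
      contained <- hsp$q_start[later] >= hsp$q_start[r] - 10 &
        hsp$q_end[later] <= hsp$q_end[r] + 10 &
        hsp$s_start[later] >= hsp$s_start[r] - 10 &
        hsp$s_end[later] <= hsp$s_end[r] + 10
      keep[later][contained] <- FALSE
    }
  }
  hsp <- hsp[keep, , drop = FALSE]
  head(hsp, params$max_hsp)
}

#' Seed-and-extend local alignment
#'
#' Finds local alignments between two DNA sequences on both strands:
#' exact `word_size`-mer seeds are grouped by diagonal, X-drop extended
#' without gaps, and surviving HSPs are polished by a banded affine-gap
#' local dynamic programme over a padded window. Alignments with
#' E-value above `evalue_max` are discarded and lower-scoring alignments
#' whose query and subject intervals are largely covered by a
#' higher-scoring one are dropped.
#'
#' @param query,subject DNA strings.
#' @param params an [alignment_params()] object.
#' @return tibble with `q_start`, `q_end`, `s_start`, `s_end` (ascending,
#'   subject-forward coordinates), `strand`, `score`, `evalue`,
#'   `identity`, `n_match`, `n_mismatch`, `n_gaps`, `aligned_length`
#'   (alignment columns).
#' @export
local_align <- function(query, subject, params = alignment_params()) {
  stopifnot(nchar(query) > 0, nchar(subject) > 0)
  nq <- nchar(query); ns <- nchar(subject)
  res <- list()
  for (strand in c("+", "-")) {
    s_use <- if (strand == "+") subject else revcomp(subject)
    hsp <- hsp_candidates(query, s_use, params)
    if (is.null(hsp)) next
    for (r in seq_len(nrow(hsp))) {
      qs_w <- max(1L, hsp$q_start[r] - params$window_pad)
      qe_w <- min(nq, hsp$q_end[r] + params$window_pad)
      ss_w <- max(1L, hsp$s_start[r] - params$window_pad)
      se_w <- min(ns, hsp$s_end[r] + params$window_pad)
      qsub <- substr(query, qs_w, qe_w)
      ssub <- substr(s_use, ss_w, se_w)
      off <- (hsp$s_start[r] - ss_w) - (hsp$q_start[r] - qs_w)
      al <- cpp_local_band(qsub, ssub, off, params$band, params$match,
                           params$mismatch, params$gap_open, params$gap_ext)
      if (al$score[1] <= 0) next
      q1 <- qs_w + al$a_start - 1L; q2 <- qs_w + al$a_end - 1L
      t1 <- ss_w + al$b_start - 1L; t2 <- ss_w + al$b_end - 1L
      if (strand == "-") {
        tmp <- t1
        t1 <- ns - t2 + 1L
        t2 <- ns - tmp + 1L
      }
      cols <- al$n_match + al$n_mismatch + al$n_del + al$n_ins
      res[[length(res) + 1L]] <- tibble(
        q_start = q1, q_end = q2, s_start = t1, s_end = t2, strand = strand,
        score = al$score,
        evalue = params$K * as.double(nq) * as.double(ns) *
          exp(-params$lambda * al$score),
        identity = al$n_match / cols, n_match = al$n_match,
        n_mismatch = al$n_mismatch, n_gaps = al$n_del + al$n_ins,
        aligned_length = cols)
    }
  }
  empty <- tibble(q_start = integer(), q_end = integer(),
                  s_start = integer(), s_end = integer(),
                  strand = character(), score = integer(), evalue = numeric(),
                  identity = numeric(), n_match = integer(),
                  n_mismatch = integer(), n_gaps = integer(),
                  aligned_length = integer())
  if (length(res) == 0) return(empty)
  h <- dplyr::bind_rows(res) |>
    dplyr::distinct(.data$q_start, .data$q_end, .data$s_start, .data$s_end,
                    .data$strand, .keep_all = TRUE) |>
    filter(.data$evalue <= params$evalue_max) |>
    arrange(desc(.data$score), .data$q_start)
  if (nrow(h) == 0) return(empty)
  # subsumption: drop a hit whose query and subject intervals are both
  # >= 50% covered by a single higher-scoring hit on the same strand
  keep <- rep(TRUE, nrow(h))
  ov <- function(s1, e1, s2, e2) {
    pmax(0L, pmin(e1, e2) - pmax(s1, s2) + 1L)
  }
  for (r in seq_len(nrow(h))) {
    if (!keep[r] || r == nrow(h)) next
    later <- (r + 1):nrow(h)
    qcov <- ov(h$q_start[later], h$q_end[later], h$q_start[r], h$q_end[r]) /
      (h$q_end[later] - h$q_start[later] + 1L)
    scov <- ov(h$s_start[later], h$s_end[later], h$s_start[r], h$s_end[r]) /
      (h$s_end[later] - h$s_start[later] + 1L)
    drop <- h$strand[later] == h$strand[r] & qcov >= 0.5 & scov >= 0.5
    keep[later][drop] <- FALSE
  }
  h[keep, , drop = FALSE]
}

#' Detect plastid-derived segments (MTPTs) in mitochondrial molecules
#'
#' Runs the local aligner with plastid DNA as query against every
#' mitochondrial molecule, orders hits by aligned length, assigns ids
#' `mtpt1`, `mtpt2`, ..., bins each hit's identity into similarity
#' classes (100%, 90-100%, 80-90%, <80%), and annotates plastid genes
#' contained in each hit (complete span inside the hit) or overlapping
#' it partially (fragments, labelled `-fra`). Reverse-strand hits carry
#' descending mitochondrial coordinates.
#'
#' @param cp one-row molecule tibble (plastid).
#' @param mt_molecules molecule tibble (mitochondrial).
#' @param params [alignment_params()].
#' @param cp_features optional plastid feature tibble for gene
#'   annotation.
#' @return tibble of hits: `id`, `aligned_length`, `mt_molecule`,
#'   `mt_start`, `mt_end`, `cp_start`, `cp_end`, `strand`,
#'   `n_mismatches`, `n_gaps`, `identity`, `similarity_class`,
#'   `contained_genes` (label string), `genes` (list column).
#' @export
find_mtpts <- function(cp, mt_molecules, params = alignment_params(),
                       cp_features = NULL) {
  stopifnot(nrow(cp) == 1)
  hits <- list()
  for (m in seq_len(nrow(mt_molecules))) {
    al <- local_align(cp$sequence, mt_molecules$sequence[m], params)
    if (nrow(al) == 0) next
    al$mt_molecule <- mt_molecules$id[m]
    hits[[length(hits) + 1L]] <- al
  }
  if (length(hits) == 0) {
    return(tibble(id = character(), aligned_length = integer(),
                  mt_molecule = character(), mt_start = integer(),
                  mt_end = integer(), cp_start = integer(),
                  cp_end = integer(), strand = character(),
                  n_mismatches = integer(), n_gaps = integer(),
                  identity = numeric(), similarity_class = character(),
                  contained_genes = character(), genes = list()))
  }
  h <- dplyr::bind_rows(hits) |>
    arrange(desc(.data$aligned_length), .data$mt_molecule, .data$s_start)
  h$id <- paste0("mtpt", seq_len(nrow(h)))
  mtc <- coords_to_table(h$s_start, h$s_end, h$strand)
  genes <- lapply(seq_len(nrow(h)), function(r) {
    if (is.null(cp_features)) {
      return(tibble(gene = character(), status = character()))
    }
    annotate_mtpt(h$q_start[r], h$q_end[r], cp_features)
  })
  tibble(
    id = h$id, aligned_length = h$aligned_length,
    mt_molecule = h$mt_molecule, mt_start = mtc$start, mt_end = mtc$end,
    cp_start = h$q_start, cp_end = h$q_end, strand = h$strand,
    n_mismatches = h$n_mismatch, n_gaps = h$n_gaps, identity = h$identity,
    similarity_class = dplyr::case_when(
      h$identity == 1 ~ "eq100",
      h$identity >= 0.9 ~ "ge90lt100",
      h$identity >= 0.8 ~ "ge80lt90",
      TRUE ~ "lt80"),
    contained_genes = vapply(genes, function(g) {
      if (nrow(g) == 0) return("/")
      paste(ifelse(g$status == "complete", g$gene, paste0(g$gene, "-fra")),
            collapse = "; ")
    }, character(1)),
    genes = genes)
}

#' Annotate genes contained in an MTPT hit
#'
#' A gene is `complete` when its full annotated span lies within the
#' hit's plastid interval, `fragment` when it overlaps partially; genes
#' with no overlap are omitted.
#'
#' @param cp_start,cp_end hit interval on the plastid genome (1-based
#'   inclusive).
#' @param cp_features plastid feature tibble.
#' @return tibble with `gene`, `status`.
#' @export
annotate_mtpt <- function(cp_start, cp_end, cp_features) {
  ov <- cp_features$start <= cp_end & cp_features$end >= cp_start
  f <- cp_features[ov, , drop = FALSE]
  if (nrow(f) == 0) return(tibble(gene = character(), status = character()))
  tibble(gene = f$gene,
         status = ifelse(f$start >= cp_start & f$end <= cp_end,
                         "complete", "fragment")) |>
    arrange(match(.data$gene, cp_features$gene))
}

#' Summarise genome coverage by homologous segments
#'
#' Per-genome homologous bp is the length of the union of hit intervals
#' (overlaps counted once, via [IRanges::reduce()]); bp intersecting
#' supplied repeat regions is reported separately, and raw (sum of
#' interval lengths, double-counting overlaps) totals are included
#' because duplicated-region hits make the two conventions differ.
#'
#' @param hits tibble from [find_mtpts()].
#' @param cp plastid molecule row.
#' @param mt_molecules mitochondrial molecule tibble.
#' @param repeat_regions optional tibble (`molecule`, `start`, `end`) of
#'   repeat regions (e.g. the plastid IRs, the mt repeat catalogue).
#' @return one-row tibble of class `homology_summary`.
#' @export
summarize_homology <- function(hits, cp, mt_molecules,
                               repeat_regions = NULL) {
  rng <- function(s, e) IRanges::IRanges(start = pmin(s, e),
                                         end = pmax(s, e))
  cp_r <- IRanges::reduce(rng(hits$cp_start, hits$cp_end))
  cp_union <- sum(IRanges::width(cp_r))
  mt_union <- 0L
  mt_raw <- 0L
  rr_mt <- 0L
  for (m in mt_molecules$id) {
    hm <- hits[hits$mt_molecule == m, , drop = FALSE]
    if (nrow(hm) == 0) next
    r <- IRanges::reduce(rng(hm$mt_start, hm$mt_end))
    mt_union <- mt_union + sum(IRanges::width(r))
    mt_raw <- mt_raw + sum(abs(hm$mt_end - hm$mt_start) + 1L)
    if (!is.null(repeat_regions)) {
      rr <- repeat_regions[repeat_regions$molecule == m, , drop = FALSE]
      if (nrow(rr) > 0) {
        rr_mt <- rr_mt +
          sum(IRanges::width(IRanges::intersect(
            r, IRanges::reduce(rng(rr$start, rr$end)))))
      }
    }
  }
  rr_cp <- 0L
  if (!is.null(repeat_regions)) {
    rr <- repeat_regions[repeat_regions$molecule == cp$id, , drop = FALSE]
    if (nrow(rr) > 0) {
      rr_cp <- sum(IRanges::width(IRanges::intersect(
        cp_r, IRanges::reduce(rng(rr$start, rr$end)))))
    }
  }
  out <- tibble(
    n_hits = nrow(hits),
    total_cp_bp = cp_union, total_mt_bp = mt_union,
    cp_fraction = round_half_up(100 * cp_union / cp$length, 2),
    mt_fraction = round_half_up(100 * mt_union / sum(mt_molecules$length), 2),
    repeat_region_cp_bp = rr_cp, repeat_region_mt_bp = rr_mt,
    raw_cp_bp = sum(hits$cp_end - hits$cp_start + 1L), raw_mt_bp = mt_raw)
  class(out) <- c("homology_summary", class(out))
  out
}
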