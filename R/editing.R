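EDIT_TYPES <- c("A to C", "A to G", "A to U", "C to A", "C to G", "C to U",
                "G to A", "G to C", "G to U", "U to A", "U to C", "U to G")

rna_base <- function(b) ifelse(b == "T", "U", b)

#' Coverage and support thresholds for site calling
#'
#' High-copy plastid genes require 20x coverage; low-copy, often lowly
#' expressed mitochondrial genes are relaxed to 10x. A candidate base
#' must be supported by at least 10% of reads. The same thresholds apply
#' to RNA-editing sites and DNA SNPs.
#'
#' @param min_cov_plastid,min_cov_mito minimal depth per organelle.
#' @param min_support minimal alternative-base read fraction, in (0, 1).
#' @return list of class `call_thresholds`.
#' @export
call_thresholds <- function(min_cov_plastid = 20L, min_cov_mito = 10L,
                            min_support = 0.10) {
  stopifnot(min_cov_plastid >= 1, min_cov_mito >= 1,
            min_support > 0, min_support < 1)
  structure(list(min_cov_plastid = as.integer(min_cov_plastid),
                 min_cov_mito = as.integer(min_cov_mito),
                 min_support = min_support), class = "call_thresholds")
}

min_cov_for <- function(organelle, thresholds) {
  ifelse(organelle == "plastid", thresholds$min_cov_plastid,
         thresholds$min_cov_mito)
}

#' Pile up reads against spliced coding sequences
#'
#' Assigns every read to its best-matching CDS (shared k-mer count, both
#' orientations; ties broken deterministically toward the
#' lexicographically first gene and flagged), aligns it end-to-end
#' within the CDS with a banded affine-gap alignment, and tallies the
#' per-column base composition. Alignment columns that are insertions in
#' the read are skipped; read deletions contribute no count.
#'
#' @param reads read tibble (`read_id`, `sequence`).
#' @param cds tibble from [extract_cds()].
#' @param k k-mer length for assignment and anchoring.
#' @param band alignment band half-width.
#' @param min_kmer_hits minimal shared k-mers to assign a read.
#' @return pileup tibble: `gene`, `cds_pos`, `ref_base`, `A`, `C`, `G`,
#'   `T`, `depth`, with attributes `n_unassigned` and `n_tied`.
#' @export
pileup_cds <- function(reads, cds, k = 15L, band = 32L, min_kmer_hits = 2L) {
  genes <- sort(cds$gene)
  cds <- cds[match(genes, cds$gene), , drop = FALSE]
  counts <- lapply(seq_len(nrow(cds)), function(i) {
    matrix(0L, nrow = 4, ncol = cds$length[i],
           dimnames = list(c("A", "C", "G", "T"), NULL))
  })
  names(counts) <- cds$gene
  n_unassigned <- 0L
  n_tied <- 0L
  for (r in seq_len(nrow(reads))) {
    s <- reads$sequence[r]
    rc <- revcomp(s)
    hits <- vapply(seq_len(nrow(cds)), function(i) {
      c(cpp_diag_vote(s, cds$sequence[i], k, 4L)$hits,
        cpp_diag_vote(rc, cds$sequence[i], k, 4L)$hits)
    }, numeric(2))
    best <- max(hits)
    if (best < min_kmer_hits) { n_unassigned <- n_unassigned + 1L; next }
    cand <- which(apply(hits, 2, max) == best)
    if (length(cand) > 1) n_tied <- n_tied + 1L
    gi <- cand[1]
    use <- if (hits[2, gi] > hits[1, gi]) rc else s
    v <- cpp_diag_vote(use, cds$sequence[gi], k, 4L)
    al <- cpp_glocal_band(use, cds$sequence[gi], v$offset, band,
                          2L, -3L, 5L, 2L)
    if (is.na(al$score[1])) { n_unassigned <- n_unassigned + 1L; next }
    gpos <- 1L                      # position in read
    lpos <- al$l_start              # position in CDS
    ops <- al$ops
    # compress runs for vectorised tallying
    rl <- rle(ops)
    for (seg in seq_along(rl$values)) {
      op <- rl$values[seg]; len <- rl$lengths[seg]
      if (op <= 1L) {               # aligned columns (match or mismatch)
        bases <- chars(substr(use, gpos, gpos + len - 1L))
        pos <- lpos:(lpos + len - 1L)
        ok <- bases %in% c("A", "C", "G", "T")
        if (any(ok)) {
          idx <- cbind(match(bases[ok], c("A", "C", "G", "T")), pos[ok])
          counts[[gi]][idx] <- counts[[gi]][idx] + 1L
        }
        gpos <- gpos + len; lpos <- lpos + len
      } else if (op == 2L) {        # insertion in read: no CDS column
        gpos <- gpos + len
      } else {                      # deletion in read: CDS column uncovered
        lpos <- lpos + len
      }
    }
  }
  out <- lapply(seq_len(nrow(cds)), function(i) {
    m <- counts[[i]]
    tibble(gene = cds$gene[i], cds_pos = seq_len(ncol(m)),
           ref_base = chars(cds$sequence[i]),
           A = m[1, ], C = m[2, ], G = m[3, ], T = m[4, ],
           depth = as.integer(colSums(m)))
  })
  out <- dplyr::bind_rows(out)
  attr(out, "n_unassigned") <- n_unassigned
  attr(out, "n_tied") <- n_tied
  out
}

# shared candidate logic: top non-reference base per qualifying column
site_candidates <- function(pileup, organelle, thresholds) {
  stopifnot(all(organelle %in% c("mito", "plastid")) ||
              all(names(organelle) != ""))
  org <- if (length(organelle) == 1) {
    rep(organelle, nrow(pileup))
  } else {
    unname(organelle[pileup$gene])
  }
  min_cov <- min_cov_for(org, thresholds)
  bm <- as.matrix(pileup[, c("A", "C", "G", "T")])
  ref_idx <- match(pileup$ref_base, c("A", "C", "G", "T"))
  nonref <- bm
  nonref[cbind(seq_len(nrow(bm)), ref_idx)] <- -1L
  top <- apply(nonref, 1, max)
  top_base <- c("A", "C", "G", "T")[apply(nonref, 1, which.max)]
  n_top <- rowSums(nonref == top & top > 0)
  ok <- pileup$depth >= min_cov & top > 0 &
    top / pileup$depth >= thresholds$min_support
  tibble(gene = pileup$gene[ok], cds_pos = pileup$cds_pos[ok],
         ref_base = pileup$ref_base[ok], alt_base = top_base[ok],
         alt_count = as.integer(top[ok]), depth = pileup$depth[ok],
         ambiguous = n_top[ok] > 1)
}

#' Call DNA SNPs from a WGS pileup
#'
#' Positions whose whole-genome (DNA) reads meet the same coverage and
#' support thresholds as editing calls are natural variants; they are
#' excluded from RNA-editing output.
#'
#' @param wgs_pileup pileup tibble built against the same CDS
#'   coordinates.
#' @param organelle `"mito"`/`"plastid"`, or a named vector by gene.
#' @param thresholds a [call_thresholds()] object.
#' @return tibble with `gene`, `cds_pos`, `alt_base`, `support`, `depth`.
#' @export
call_snps <- function(wgs_pileup, organelle = "mito",
                      thresholds = call_thresholds()) {
  s <- site_candidates(wgs_pileup, organelle, thresholds)
  tibble(gene = s$gene, cds_pos = s$cds_pos, alt_base = s$alt_base,
         support = s$alt_count / s$depth, depth = s$depth)
}

#' Call RNA-editing sites from an RNA pileup
#'
#' A site is called when its depth meets the organelle-specific coverage
#' floor, the most frequent non-reference base reaches the support
#' threshold, and the position is not a DNA SNP. Editing efficiency is
#' the edited-base count over total depth. Reference and edited T are
#' reported as U in the 12 edit-type labels. Positions where two
#' non-reference bases tie are returned flagged `ambiguous` (both
#' candidates in `edit_type`, excluded from type totals).
#'
#' @param rna_pileup pileup tibble.
#' @param snps tibble from [call_snps()] (or any tibble with `gene`,
#'   `cds_pos`), or `NULL`.
#' @param organelle `"mito"`/`"plastid"`, or a named vector by gene.
#' @param thresholds a [call_thresholds()] object.
#' @return tibble of class `editing_sites`: `gene`, `cds_pos`,
#'   `ref_base`, `edited_base`, `edit_type`, `efficiency`, `depth`,
#'   `codon_pos`, `ambiguous`, `snp_excluded` (always `FALSE`; excluded
#'   sites are dropped and counted in attribute `n_snp_excluded`).
#' @export
call_editing_sites <- function(rna_pileup, snps = NULL, organelle = "mito",
                               thresholds = call_thresholds()) {
  s <- site_candidates(rna_pileup, organelle, thresholds)
  excl <- rep(FALSE, nrow(s))
  if (!is.null(snps) && nrow(snps) > 0) {
    key <- paste(s$gene, s$cds_pos)
    excl <- key %in% paste(snps$gene, snps$cds_pos)
  }
  n_excl <- sum(excl)
  s <- s[!excl, , drop = FALSE]
  out <- tibble(
    gene = s$gene, cds_pos = s$cds_pos, ref_base = s$ref_base,
    edited_base = ifelse(s$ambiguous, NA_character_, s$alt_base),
    edit_type = ifelse(
      s$ambiguous,
      paste0(rna_base(s$ref_base), " to ?"),
      paste(rna_base(s$ref_base), "to", rna_base(s$alt_base))),
    efficiency = s$alt_count / s$depth, depth = s$depth,
    codon_pos = ((s$cds_pos - 1L) %% 3L) + 1L,
    ambiguous = s$ambiguous, snp_excluded = FALSE)
  attr(out, "n_snp_excluded") <- n_excl
  class(out) <- c("editing_sites", class(out))
  out
}

#' Summarise editing sites
#'
#' Counts per gene and per edit type (over the 12 ordered types,
#' ambiguous sites excluded from type totals), plus an efficiency
#' histogram over \[0, 0.5), \[0.5, 0.8), \[0.8, 0.9), \[0.9, 1\] and the
#' percentage of sites with efficiency above 0.9 (2 decimals).
#'
#' @param sites tibble from [call_editing_sites()] (possibly empty).
#' @return list of class `editing_summary` with `per_gene`, `per_type`,
#'   `efficiency_hist`, `n_sites`, `pct_above_0.9`.
#' @export
summarize_editing <- function(sites) {
  unamb <- sites[!sites$ambiguous, , drop = FALSE]
  per_gene <- if (nrow(unamb) == 0) {
    tibble(gene = character(), n = integer())
  } else {
    count(unamb, .data$gene, name = "n")
  }
  per_type <- tibble(edit_type = EDIT_TYPES,
                     n = vapply(EDIT_TYPES,
                                function(t) sum(unamb$edit_type == t),
                                integer(1), USE.NAMES = FALSE))
  edges <- c(0, 0.5, 0.8, 0.9, 1)
  labs <- c("[0,0.5)", "[0.5,0.8)", "[0.8,0.9)", "[0.9,1]")
  hist_n <- vapply(seq_len(4), function(b) {
    hi <- if (b == 4) unamb$efficiency <= edges[b + 1] else
      unamb$efficiency < edges[b + 1]
    sum(unamb$efficiency >= edges[b] & hi)
  }, integer(1))
  n <- nrow(unamb)
  structure(list(
    per_gene = per_gene,
    per_type = per_type,
    efficiency_hist = tibble(bin = labs, n = hist_n),
    n_sites = n,
    `pct_above_0.9` = if (n == 0) 0 else
      round_half_up(100 * sum(unamb$efficiency > 0.9) / n, 2)),
    class = "editing_summary")
}

#' @export
print.editing_summary <- function(x, ...) {
  cat("<editing_summary>", x$n_sites, "sites;",
      x$`pct_above_0.9`, "% above 0.9 efficiency\n")
  top <- x$per_type[order(-x$per_type$n), ][1, ]
  if (x$n_sites > 0) {
    cat("  most common type:", top$edit_type, "(", top$n, ")\n")
  }
  invisible(x)
}
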