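#' Simulation configuration
#'
#' Bundles every knob of the synthetic organelle data generator. With the
#' seed fixed, all generator outputs are byte-identical across runs.
#'
#' Defaults emulate the study system at desk scale: a bipartite
#' mitochondrial genome (two molecules, the larger circular and branching
#' in reality; here both circular), a much smaller plastid genome, a
#' catalogue of direct and inverted repeats from a few hundred bp up to
#' several kb, plastid-derived segments (MTPTs) at varying divergence, and
#' C-to-U-dominated editing in protein-coding genes.
#'
#' @param seed integer RNG seed; all randomness derives from it.
#' @param mt_lengths integer vector of mitochondrial molecule lengths (bp).
#' @param cp_length plastid molecule length (bp).
#' @param gc_fraction background GC fraction in \[0, 1\].
#' @param mt_topology topology per mt molecule (`"circular"`/`"linear"`).
#' @param repeat_specs tibble with columns `length` (bp), `orientation`
#'   (`"direct"`/`"inverted"`), `placement` (`"intra"`/`"inter"`).
#' @param mtpt_specs tibble with columns `length` (bp), `n_sub`, `n_indel`
#'   (planted substitution / 1-bp indel counts).
#' @param conformation_mixture named numeric vector in \[0, 1\]: for each
#'   repeat id (`"R1"`, `"R2"`, ... in `repeat_specs` order), the fraction
#'   of spanning reads drawn from the crossover (alternative) conformation.
#' @param n_genes_mt,n_genes_cp number of protein-coding genes planted on
#'   the mitochondrial / plastid molecules.
#' @param gene_length_range range of planted CDS lengths (rounded to
#'   codons).
#' @param editing_specs tibble with columns `gene`, `cds_pos`, `ref_base`,
#'   `edited_base`, `efficiency`; or `NULL` to auto-plant (see
#'   [simulate_genomes()]).
#' @param snp_specs tibble with columns `gene`, `cds_pos`, `alt_base`; or
#'   `NULL`.
#' @param read_mean,read_sd mean and log-scale spread of the (log-normal)
#'   long-read length distribution (bp).
#' @param sub_rate,ins_rate,del_rate per-base read error rates in \[0, 1\].
#' @param n_reads number of background long reads.
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(seed = 1L,
                       mt_lengths = c(40000L, 25000L),
                       cp_length = 15000L,
                       gc_fraction = 0.45,
                       mt_topology = c("circular", "circular"),
                       repeat_specs = tibble(
                         length = c(2000L, 300L),
                         orientation = c("direct", "inverted"),
                         placement = c("intra", "intra")),
                       mtpt_specs = tibble(
                         length = c(1500L, 500L),
                         n_sub = c(5L, 10L),
                         n_indel = c(0L, 2L)),
                       conformation_mixture = NULL,
                       n_genes_mt = 12L, n_genes_cp = 8L,
                       gene_length_range = c(300L, 900L),
                       editing_specs = NULL,
                       snp_specs = NULL,
                       read_mean = 6000, read_sd = 0.4,
                       sub_rate = 0.05, ins_rate = 0.015, del_rate = 0.015,
                       n_reads = 500L) {
  stopifnot(is.numeric(seed), length(seed) == 1,
            all(mt_lengths >= 1000), cp_length >= 1000,
            gc_fraction >= 0, gc_fraction <= 1,
            length(mt_topology) == length(mt_lengths),
            all(mt_topology %in% c("circular", "linear")),
            sub_rate >= 0, sub_rate <= 1, ins_rate >= 0, ins_rate <= 1,
            del_rate >= 0, del_rate <= 1, read_mean >= 200)
  if (!is.null(repeat_specs)) {
    stopifnot(all(c("length", "orientation", "placement") %in%
                    names(repeat_specs)),
              all(repeat_specs$orientation %in% c("direct", "inverted")),
              all(repeat_specs$placement %in% c("intra", "inter")),
              all(repeat_specs$length >= 20))
  }
  if (!is.null(mtpt_specs)) {
    stopifnot(all(c("length", "n_sub", "n_indel") %in% names(mtpt_specs)),
              all(mtpt_specs$length >= 30),
              all(mtpt_specs$n_sub >= 0), all(mtpt_specs$n_indel >= 0))
  }
  if (!is.null(conformation_mixture)) {
    stopifnot(!is.null(names(conformation_mixture)),
              all(conformation_mixture >= 0),
              all(conformation_mixture <= 1))
  }
  if (!is.null(editing_specs)) {
    stopifnot(all(c("gene", "cds_pos", "ref_base", "edited_base",
                    "efficiency") %in% names(editing_specs)),
              all(editing_specs$efficiency >= 0),
              all(editing_specs$efficiency <= 1))
  }
  structure(list(
    seed = as.integer(seed), mt_lengths = as.integer(mt_lengths),
    cp_length = as.integer(cp_length), gc_fraction = gc_fraction,
    mt_topology = mt_topology, repeat_specs = repeat_specs,
    mtpt_specs = mtpt_specs, conformation_mixture = conformation_mixture,
    n_genes_mt = as.integer(n_genes_mt), n_genes_cp = as.integer(n_genes_cp),
    gene_length_range = as.integer(gene_length_range),
    editing_specs = editing_specs, snp_specs = snp_specs,
    read_mean = read_mean, read_sd = read_sd,
    sub_rate = sub_rate, ins_rate = ins_rate, del_rate = del_rate,
    n_reads = as.integer(n_reads)), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config> seed", x$seed, "\n")
  cat("  mt molecules:", paste(x$mt_lengths, collapse = ", "), "bp (",
      paste(x$mt_topology, collapse = ", "), ")\n")
  cat("  cp molecule:", x$cp_length, "bp circular\n")
  cat("  repeats:", if (is.null(x$repeat_specs)) 0 else nrow(x$repeat_specs),
      " mtpts:", if (is.null(x$mtpt_specs)) 0 else nrow(x$mtpt_specs), "\n")
  cat("  read errors sub/ins/del:", x$sub_rate, x$ins_rate, x$del_rate, "\n")
  invisible(x)
}
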