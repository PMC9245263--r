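#' Run the full pipeline on simulated data
#'
#' End-to-end orchestration used for fixtures and reproducibility
#' checks: simulates genomes and reads from `config`, finds and
#' classifies repeats, quantifies recombination for each repeat with a
#' configured conformation mixture, detects MTPTs and summarises genome
#' homology, verifies integration of the first MTPT, simulates RNA/WGS
#' reads, and calls SNPs and editing sites. All result tables are
#' written as TSV into `out_dir` together with a JSON run report
#' containing the full parameter set; reruns with the same config are
#' byte-identical.
#'
#' @param config a [sim_config()].
#' @param out_dir output directory (created if missing).
#' @param n_spanning_reads spanning reads simulated per mixture repeat.
#' @param editing list of options for the editing stage: `n_sites`,
#'   `n_snps`, `depth`.
#' @param thresholds a [call_thresholds()].
#' @return invisibly, a list with all in-memory results.
#' @export
run_pipeline <- function(config, out_dir,
                         n_spanning_reads = 200L,
                         editing = list(n_sites = 40L, n_snps = 5L,
                                        depth = 50L),
                         thresholds = call_thresholds()) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- function(d, name) {
    utils::write.table(d, file.path(out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }

  sim <- simulate_genomes(config)
  mols <- sim$molecules
  write_fasta(mols, file.path(out_dir, "genomes.fasta"))

  pairs <- find_repeats(mols, min_len = 100L)
  pairs <- classify_repeats(pairs)
  write_repeat_table(pairs, file.path(out_dir, "repeats.tsv"))

  # recombination support per planted repeat with a configured mixture
  support <- list()
  mix <- config$conformation_mixture
  if (!is.null(mix) && nrow(sim$truth$repeats) > 0) {
    for (rid in names(mix)) {
      rp <- sim$truth$repeats[sim$truth$repeats$repeat_id == rid, ]
      if (nrow(rp) == 0) next
      sr <- simulate_spanning_reads(
        mols, rp, n = n_spanning_reads, alt_fraction = mix[[rid]],
        sub_rate = config$sub_rate, ins_rate = config$ins_rate,
        del_rate = config$del_rate, seed = child_seed(config$seed, rid))
      cs <- build_conformations(mols, rp)
      calls <- classify_spanning_reads(sr$reads, cs)
      calls$repeat_id <- rid
      support[[rid]] <- quantify_recombination(calls, rid)
    }
  }
  support <- dplyr::bind_rows(support)
  if (nrow(support) > 0) tsv(support, "recombination.tsv")

  cp <- mols[mols$organelle == "plastid", ]
  mt <- mols[mols$organelle == "mito", ]
  cp_features <- sim$features[sim$features$molecule == cp$id, ]
  hits <- find_mtpts(cp, mt, cp_features = cp_features)
  tsv(select(hits, -"genes"), "mtpt_hits.tsv")
  writeLines(
    c(sprintf("%s\t%d\t%d\t%s", hits$mt_molecule,
              pmin(hits$mt_start, hits$mt_end) - 1L,
              pmax(hits$mt_start, hits$mt_end), hits$id)),
    file.path(out_dir, "mtpt_hits.bed"))
  hsum <- summarize_homology(hits, cp, mt)
  tsv(hsum, "homology_summary.tsv")

  verify <- NULL
  if (nrow(hits) > 0) {
    lr <- simulate_long_reads(mols, config, truth = sim$truth)
    verify <- verify_mtpt_integration(
      lr$reads, mols, hits$mt_molecule[1],
      min(hits$mt_start[1], hits$mt_end[1]),
      max(hits$mt_start[1], hits$mt_end[1]), flank = 500L)
  }

  cds <- extract_cds(mols, sim$features)
  specs <- plant_site_specs(cds, n_sites = editing$n_sites,
                            n_snps = editing$n_snps,
                            seed = child_seed(config$seed, "specs"))
  rw <- simulate_rnaseq_wgs(cds, specs$editing_specs, specs$snp_specs,
                            depth = editing$depth,
                            seed = child_seed(config$seed, "rnawgs"))
  org <- setNames(cds$organelle, cds$gene)
  rna_pile <- pileup_cds(rw$rna_reads, cds)
  wgs_pile <- pileup_cds(rw$wgs_reads, cds)
  snps <- call_snps(wgs_pile, org, thresholds)
  sites <- call_editing_sites(rna_pile, snps, org, thresholds)
  esum <- summarize_editing(sites)
  tsv(sites, "editing_sites.tsv")
  tsv(esum$per_gene, "editing_per_gene.tsv")
  tsv(esum$per_type, "editing_per_type.tsv")
  tsv(esum$efficiency_hist, "editing_efficiency_hist.tsv")

  report <- list(
    package = "organellr",
    version = as.character(utils::packageVersion("organellr")),
    seed = config$seed,
    config = config[setdiff(names(config),
                            c("repeat_specs", "mtpt_specs", "editing_specs",
                              "snp_specs"))],
    repeat_specs = config$repeat_specs,
    mtpt_specs = config$mtpt_specs,
    thresholds = unclass(thresholds),
    n_spanning_reads = n_spanning_reads,
    editing_options = editing,
    n_repeats_found = nrow(pairs),
    n_mtpt_hits = nrow(hits),
    n_editing_sites = nrow(sites),
    mtpt1_verified = if (is.null(verify)) NA else verify$verified)
  jsonlite::write_json(report, file.path(out_dir, "run_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(sim = sim, repeats = pairs, support = support,
                 mtpt_hits = hits, homology_summary = hsum,
                 mtpt1_verification = verify, snps = snps, sites = sites,
                 editing_summary = esum))
}
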