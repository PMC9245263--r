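BASES <- c("A", "C", "G", "T")

# apply per-base substitution / 1-bp insertion / deletion errors
mutate_read <- function(s, sub_rate, ins_rate, del_rate) {
  v <- chars(s)
  if (del_rate > 0) v <- v[runif(length(v)) >= del_rate]
  if (sub_rate > 0 && length(v) > 0) {
    m <- which(runif(length(v)) < sub_rate)
    if (length(m)) {
      v[m] <- vapply(v[m], function(b) sample(setdiff(BASES, b), 1),
                     character(1), USE.NAMES = FALSE)
    }
  }
  if (ins_rate > 0 && length(v) > 0) {
    m <- which(runif(length(v)) < ins_rate)
    for (p in rev(m)) v <- append(v, sample(BASES, 1), after = p)
  }
  paste(v, collapse = "")
}

#' Simulate long reads from genome molecules
#'
#' Read lengths follow a log-normal distribution (median `read_mean`,
#' log-sd `read_sd`) truncated to \[200, molecule length\]; start
#' positions are uniform; circular molecules yield reads crossing the
#' origin; each read is emitted from a random strand. When a
#' `conformation_mixture` is set in the config and planted repeat truth
#' is supplied, a read whose sampled interval fully spans a repeat's
#' first copy plus `flank` bp on both sides is re-derived, with the
#' configured probability, from the crossover (alternative) conformation
#' at that locus; its conformation is recorded in the origin table.
#'
#' @param molecules molecule tibble.
#' @param config a [sim_config()]; error rates, read-length model, count
#'   and mixture are taken from it.
#' @param truth optional truth list from [simulate_genomes()] (needed for
#'   mixture-aware reads).
#' @param n_reads override for `config$n_reads`.
#' @param flank spanning definition used for the mixture rule (bp).
#' @return list with `reads` (tibble `read_id`, `sequence`) and `origins`
#'   (tibble `read_id`, `molecule`, `start`, `end`, `strand`,
#'   `conformation`, `repeat_id`).
#' @export
simulate_long_reads <- function(molecules, config, truth = NULL,
                                n_reads = NULL, flank = 1000L) {
  stopifnot(nrow(molecules) > 0)
  withr::local_seed(child_seed(config$seed, "long_reads"))
  n_reads <- if (is.null(n_reads)) config$n_reads else n_reads
  mix <- config$conformation_mixture
  reps <- if (!is.null(truth)) truth$repeats else NULL

  probs <- molecules$length / sum(molecules$length)
  warned <- FALSE
  out <- vector("list", n_reads)
  orig <- vector("list", n_reads)
  for (i in seq_len(n_reads)) {
    mi <- sample.int(nrow(molecules), 1, prob = probs)
    n <- molecules$length[mi]
    len <- round(rlnorm(1, log(config$read_mean), config$read_sd))
    if (len > n) {
      if (!warned && molecules$topology[mi] == "linear") {
        warning("requested read length exceeds linear molecule ",
                molecules$id[mi], "; reads truncated")
        warned <- TRUE
      }
      len <- n
    }
    len <- max(200L, len)
    circ <- molecules$topology[mi] == "circular"
    start <- if (circ) sample.int(n, 1) else sample.int(n - len + 1L, 1)
    end <- start + len - 1L
    strand <- sample(c("+", "-"), 1)
    conformation <- NA_character_
    rep_id <- NA_character_
    s <- NULL
    if (!is.null(mix) && !is.null(reps) && nrow(reps) > 0) {
      for (k in seq_len(nrow(reps))) {
        rp <- reps[k, ]
        f <- mix[rp$repeat_id]
        if (is.na(f) || rp$molecule1 != molecules$id[mi]) next
        if (start <= rp$start1 - flank && end >= rp$end1 + flank) {
          conformation <- if (runif(1) < f) "alternative" else "major"
          rep_id <- rp$repeat_id
          if (conformation == "alternative") {
            s <- crossover_read(molecules, rp, start, end)
          }
          break
        }
      }
    }
    if (is.null(s)) {
      s <- as.character(mol_substr(molecules$sequence[mi], start, end,
                                   molecules$topology[mi]))
    }
    if (strand == "-") s <- revcomp(s)
    s <- mutate_read(s, config$sub_rate, config$ins_rate, config$del_rate)
    rid <- sprintf("lr%06d", i)
    out[[i]] <- tibble(read_id = rid, sequence = s)
    orig[[i]] <- tibble(read_id = rid, molecule = molecules$id[mi],
                        start = start, end = end, strand = strand,
                        conformation = conformation, repeat_id = rep_id)
  }
  list(reads = dplyr::bind_rows(out), origins = dplyr::bind_rows(orig))
}

# sequence of a read spanning copy 1 of `rp` in the crossover conformation:
# upstream context of copy 1, the repeat, then downstream context of copy 2
# (reverse-complemented upstream context for an inverted copy 2)
crossover_read <- function(molecules, rp, start, end) {
  m1 <- molecules[molecules$id == rp$molecule1, ]
  m2 <- molecules[molecules$id == rp$molecule2, ]
  up <- as.character(mol_substr(m1$sequence, start, rp$end1, m1$topology))
  down_len <- end - rp$end1
  down <- if (rp$orientation == "direct") {
    as.character(mol_substr(m2$sequence, rp$end2 + 1L, rp$end2 + down_len,
                            m2$topology))
  } else {
    revcomp(as.character(mol_substr(m2$sequence, rp$start2 - down_len,
                                    rp$start2 - 1L, m2$topology)))
  }
  paste0(up, down)
}

#' Simulate reads that fully span a repeat locus
#'
#' The targeted generator behind conformation-frequency experiments: every
#' read covers the repeat plus at least `flank` bp on each side, plus a
#' random extra margin of up to `margin` bp. Each read is drawn from the
#' crossover (alternative) conformation with probability `alt_fraction`,
#' otherwise from the major conformation. With `junctions = "copy1"`
#' (default) major reads show the m1 junction and alternative reads the
#' s1 junction, so the alternative-read count is Binomial(n,
#' `alt_fraction`); with `"both"` the junction within each class is
#' sampled uniformly (m1/m2, s1/s2).
#'
#' @param molecules molecule tibble.
#' @param rp one-row repeat tibble (truth row or [find_repeats()] row).
#' @param n number of reads.
#' @param alt_fraction crossover-conformation probability in \[0, 1\].
#' @param flank guaranteed flank coverage (bp).
#' @param margin maximal random extra flank (bp).
#' @param junctions `"copy1"` or `"both"`.
#' @param sub_rate,ins_rate,del_rate read error rates.
#' @param seed integer seed.
#' @return list with `reads` tibble and `truth` tibble (`read_id`,
#'   `conformation`, `path`).
#' @export
simulate_spanning_reads <- function(molecules, rp, n, alt_fraction,
                                    flank = 1000L, margin = 400L,
                                    junctions = c("copy1", "both"),
                                    sub_rate = 0, ins_rate = 0, del_rate = 0,
                                    seed = 1L) {
  junctions <- match.arg(junctions)
  stopifnot(alt_fraction >= 0, alt_fraction <= 1, n >= 1)
  withr::local_seed(child_seed(seed, "spanning"))
  cs <- build_conformations(molecules, rp, flank = flank + margin)
  reads <- vector("list", n)
  tr <- vector("list", n)
  for (i in seq_len(n)) {
    alt <- runif(1) < alt_fraction
    path <- if (junctions == "copy1") {
      if (alt) "s1" else "m1"
    } else {
      if (alt) sample(c("s1", "s2"), 1) else sample(c("m1", "m2"), 1)
    }
    tmpl <- cs$paths[[path]]
    a <- sample.int(margin + 1L, 1) - 1L   # extra kept on the left
    b <- sample.int(margin + 1L, 1) - 1L
    s <- substr(tmpl, margin - a + 1L, nchar(tmpl) - margin + b)
    if (sample(c(TRUE, FALSE), 1)) s <- revcomp(s)
    s <- mutate_read(s, sub_rate, ins_rate, del_rate)
    rid <- sprintf("sp%06d", i)
    reads[[i]] <- tibble(read_id = rid, sequence = s)
    tr[[i]] <- tibble(read_id = rid,
                      conformation = if (alt) "alternative" else "major",
                      path = path)
  }
  list(reads = dplyr::bind_rows(reads), truth = dplyr::bind_rows(tr))
}

#' Plant RNA-editing and SNP specifications on simulated genes
#'
#' Chooses distinct CDS positions and draws editing types; by default
#' C-to-U dominates (as in plant organelles) with the remaining 11 types
#' sharing the rest. SNP specs are drawn the same way at positions not
#' used by editing specs.
#'
#' @param cds tibble from [extract_cds()].
#' @param n_sites number of editing sites.
#' @param n_snps number of DNA SNPs.
#' @param efficiency_range editing-efficiency range (uniform draw).
#' @param prop_c_to_u fraction of sites that are C-to-U.
#' @param seed integer seed.
#' @return list with `editing_specs` and `snp_specs` tibbles.
#' @export
plant_site_specs <- function(cds, n_sites, n_snps = 0,
                             efficiency_range = c(0.2, 1),
                             prop_c_to_u = 0.7, seed = 1L) {
  withr::local_seed(child_seed(seed, "site_specs"))
  pool <- dplyr::bind_rows(lapply(seq_len(nrow(cds)), function(i) {
    v <- chars(cds$sequence[i])
    # keep start/stop codons intact
    keep <- seq(4L, length(v) - 3L)
    tibble(gene = cds$gene[i], cds_pos = keep, ref_base = v[keep])
  }))
  pool <- pool[sample.int(nrow(pool)), ]
  total <- n_sites + n_snps
  if (total > nrow(pool)) stop("not enough CDS positions to plant sites")
  take_c <- pool$ref_base == "C"
  n_cu <- min(round(n_sites * prop_c_to_u), sum(take_c))
  cu <- pool[take_c, ][seq_len(n_cu), ]
  rest <- dplyr::anti_join(pool, cu, by = c("gene", "cds_pos"))
  oth <- rest[seq_len(total - n_cu), ]
  picks <- dplyr::bind_rows(cu, oth)
  picks$alt <- vapply(picks$ref_base,
                      function(b) sample(setdiff(BASES, b), 1),
                      character(1), USE.NAMES = FALSE)
  picks$alt[seq_len(n_cu)] <- "T"
  ed <- picks[seq_len(n_sites), ]
  sn <- if (n_snps > 0) picks[n_sites + seq_len(n_snps), ] else NULL
  list(
    editing_specs = tibble(
      gene = ed$gene, cds_pos = ed$cds_pos, ref_base = ed$ref_base,
      edited_base = ed$alt,
      efficiency = runif(n_sites, efficiency_range[1], efficiency_range[2])),
    snp_specs = if (is.null(sn)) {
      tibble(gene = character(), cds_pos = integer(), alt_base = character())
    } else {
      tibble(gene = sn$gene, cds_pos = sn$cds_pos, alt_base = sn$alt)
    })
}

#' Simulate RNA-seq and WGS reads over spliced coding sequences
#'
#' RNA reads are drawn from the spliced CDS (sense strand, then emitted
#' from both strands); WGS reads are drawn from the DNA-level CDS. Planted
#' SNPs are fixed differences present in both read sets; planted editing
#' sites appear only in RNA reads. With `efficiency_model = "exact"`
#' (default) the number of edited reads at a site is `round(efficiency *
#' n_covering)` with the carrying reads sampled at random, so planted
#' truth is recoverable at the stated efficiency; `"binomial"` draws each
#' covering read independently.
#'
#' @param cds tibble from [extract_cds()].
#' @param editing_specs tibble (`gene`, `cds_pos`, `ref_base`,
#'   `edited_base`, `efficiency`).
#' @param snp_specs tibble (`gene`, `cds_pos`, `alt_base`) or `NULL`.
#' @param depth per-base target depth.
#' @param read_length read length in bp, or `NA` for full-CDS reads
#'   (exact per-column depth).
#' @param sub_rate,ins_rate,del_rate sequencing error rates.
#' @param efficiency_model `"exact"` or `"binomial"`.
#' @param seed integer seed.
#' @return list with `rna_reads`, `wgs_reads` (read tibbles) and `truth`
#'   (realised per-site coverage and edited-read counts).
#' @export
simulate_rnaseq_wgs <- function(cds, editing_specs, snp_specs = NULL,
                                depth = 50L, read_length = NA,
                                sub_rate = 0, ins_rate = 0, del_rate = 0,
                                efficiency_model = c("exact", "binomial"),
                                seed = 1L) {
  efficiency_model <- match.arg(efficiency_model)
  withr::local_seed(child_seed(seed, "rnaseq_wgs"))
  if (!is.null(editing_specs) && nrow(editing_specs) > 0) {
    idx <- match(editing_specs$gene, cds$gene)
    if (anyNA(idx)) {
      stop("editing spec outside any PCG: ",
           paste(unique(editing_specs$gene[is.na(idx)]), collapse = ", "))
    }
    if (any(editing_specs$cds_pos > cds$length[idx]) ||
        any(editing_specs$cds_pos < 1)) {
      stop("editing spec position outside its PCG")
    }
    ref_at <- substr(cds$sequence[idx], editing_specs$cds_pos,
                     editing_specs$cds_pos)
    if (!all(ref_at == editing_specs$ref_base)) {
      stop("editing spec ref base does not match the CDS")
    }
  }

  dna <- setNames(cds$sequence, cds$gene)
  if (!is.null(snp_specs) && nrow(snp_specs) > 0) {
    for (i in seq_len(nrow(snp_specs))) {
      g <- snp_specs$gene[i]
      substr(dna[[g]], snp_specs$cds_pos[i], snp_specs$cds_pos[i]) <-
        snp_specs$alt_base[i]
    }
  }

  draw_reads <- function(src, prefix) {
    out <- list()
    k <- 0L
    for (g in names(src)) {
      len <- nchar(src[[g]])
      if (is.na(read_length) || read_length >= len) {
        starts <- rep(1L, depth); ends <- rep(len, depth)
      } else {
        nr <- ceiling(depth * len / read_length)
        starts <- sample.int(len - read_length + 1L, nr, replace = TRUE)
        ends <- starts + read_length - 1L
      }
      for (i in seq_along(starts)) {
        k <- k + 1L
        out[[k]] <- tibble(read_id = sprintf("%s%06d", prefix, k), gene = g,
                           start = starts[i], end = ends[i],
                           sequence = substr(src[[g]], starts[i], ends[i]))
      }
    }
    dplyr::bind_rows(out)
  }

  wgs <- draw_reads(dna, "wgs")
  rna <- draw_reads(dna, "rna")

  # plant edits on RNA reads
  ed_truth <- NULL
  if (!is.null(editing_specs) && nrow(editing_specs) > 0) {
    ed_truth <- editing_specs
    ed_truth$n_covering <- 0L
    ed_truth$n_edited <- 0L
    for (i in seq_len(nrow(editing_specs))) {
      e <- editing_specs[i, ]
      cov <- which(rna$gene == e$gene & rna$start <= e$cds_pos &
                     rna$end >= e$cds_pos)
      m <- length(cov)
      n_ed <- if (efficiency_model == "exact") {
        as.integer(round(e$efficiency * m))
      } else {
        rbinom(1, m, e$efficiency)
      }
      hit <- if (n_ed > 0) sample(cov, n_ed) else integer()
      for (r in hit) {
        p <- e$cds_pos - rna$start[r] + 1L
        substr(rna$sequence[r], p, p) <- e$edited_base
      }
      ed_truth$n_covering[i] <- m
      ed_truth$n_edited[i] <- n_ed
    }
  }

  finish <- function(d) {
    strand <- sample(c("+", "-"), nrow(d), replace = TRUE)
    seqs <- d$sequence
    flip <- strand == "-"
    if (any(flip)) seqs[flip] <- revcomp(seqs[flip])
    if (sub_rate > 0 || ins_rate > 0 || del_rate > 0) {
      seqs <- vapply(seqs, mutate_read, character(1),
                     sub_rate, ins_rate, del_rate, USE.NAMES = FALSE)
    }
    tibble(read_id = d$read_id, gene = d$gene, start = d$start, end = d$end,
           strand = strand, sequence = seqs)
  }

  list(rna_reads = finish(rna), wgs_reads = finish(wgs),
       truth = list(editing = ed_truth, snps = snp_specs))
}
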