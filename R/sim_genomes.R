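#' Simulate an organelle genome pair with planted truth
#'
#' Generates mitochondrial molecules and a plastid molecule of i.i.d.
#' background sequence at the configured GC fraction, then plants
#' structural elements largest-first so space never fragments under a
#' placeable configuration: exact repeat pairs (direct or inverted,
#' intra- or inter-molecule) with boundary guard bases forced to
#' mismatch so the planted coordinates are exactly the maximal repeat;
#' plastid-derived segments (MTPTs) copied from the plastid molecule
#' into a mitochondrial molecule with exactly the requested number of
#' substitutions and 1-bp indels; and simple open reading frames (ATG
#' start, no internal stop, TAA stop, length a multiple of 3) recorded
#' as PCG features.
#'
#' All placements are recorded in the returned truth object. With the
#' same config (including seed) the output is byte-identical.
#'
#' @param config a [sim_config()] object.
#' @return a list with elements `molecules` (molecule tibble, plastid
#'   last), `features` (feature tibble), and `truth` (list with tibbles
#'   `repeats`, `mtpts`, plus `mixture`).
#' @export
simulate_genomes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::local_seed(config$seed)

  n_mt <- length(config$mt_lengths)
  mol_ids <- c(paste0("mt", seq_len(n_mt)), "cp")
  lens <- c(config$mt_lengths, config$cp_length)
  topo <- c(config$mt_topology, "circular")
  org <- c(rep("mito", n_mt), "plastid")
  seqs <- lapply(lens, function(n) chars(random_dna(n, config$gc_fraction)))
  names(seqs) <- mol_ids

  occupied <- lapply(mol_ids, function(i) tibble(start = integer(),
                                                 end = integer()))
  names(occupied) <- mol_ids
  claim <- function(mol, s, e) {
    occupied[[mol]] <<- dplyr::bind_rows(occupied[[mol]],
                                         tibble(start = s, end = e))
  }
  free_slot <- function(mol, len, margin = 30L, what = "element") {
    n <- lens[match(mol, mol_ids)]
    occ <- occupied[[mol]]
    # enumerate free gaps between occupied intervals (margin-padded)
    if (nrow(occ) > 0) {
      ir <- IRanges::reduce(IRanges::IRanges(
        pmax(1L, occ$start - margin), pmin(n, occ$end + margin)))
      gs <- c(1L, IRanges::end(ir) + 1L)
      ge <- c(IRanges::start(ir) - 1L, n)
    } else {
      gs <- 1L; ge <- n
    }
    gs <- pmax(gs, margin + 1L)
    ge <- pmin(ge, n - margin)
    n_starts <- ge - gs - len + 2L      # valid start positions per gap
    ok <- which(n_starts > 0L)
    if (length(ok) == 0) {
      stop("could not place ", what, " (length ", len, ") on ", mol,
           " without overlap")
    }
    g <- if (length(ok) == 1) ok else
      sample(ok, 1L, prob = n_starts[ok])
    s <- gs[g] + sample.int(n_starts[g], 1L) - 1L
    c(s, s + len - 1L)
  }

  # --- repeat pairs ----------------------------------------------------
  rep_truth <- list()
  if (!is.null(config$repeat_specs) && nrow(config$repeat_specs) > 0) {
    for (i in order(-config$repeat_specs$length)) {   # place longest first
      spec <- config$repeat_specs[i, ]
      rid <- paste0("R", i)
      rep_seq <- random_dna(spec$length, config$gc_fraction)
      mol1 <- mol_ids[1]
      mol2 <- if (spec$placement == "inter" && n_mt > 1) mol_ids[2] else mol1
      s1 <- free_slot(mol1, spec$length, what = paste0("repeat ", rid))
      s2 <- free_slot(mol2, spec$length, what = paste0("repeat ", rid))
      # canonical order: copy1 before copy2
      if (mol1 == mol2 && s2[1] < s1[1]) { tmp <- s1; s1 <- s2; s2 <- tmp }
      copy2 <- if (spec$orientation == "inverted") revcomp(rep_seq) else rep_seq
      seqs[[mol1]][s1[1]:s1[2]] <- chars(rep_seq)
      seqs[[mol2]][s2[1]:s2[2]] <- chars(copy2)
      claim(mol1, s1[1], s1[2]); claim(mol2, s2[1], s2[2])
      # guard bases: force mismatches just outside both copies so the
      # planted interval is the maximal exact repeat
      force_diff <- function(molA, pA, molB, pB, complemented = FALSE) {
        a <- seqs[[molA]][pA]
        b <- seqs[[molB]][pB]
        bb <- if (complemented) chartr("ACGT", "TGCA", b) else b
        if (identical(a, bb)) {
          repl <- sample(setdiff(c("A", "C", "G", "T"),
                                 c(bb, if (complemented)
                                   chartr("ACGT", "TGCA", a) else a)), 1)
          seqs[[molB]][pB] <<- if (complemented)
            chartr("ACGT", "TGCA", repl) else repl
        }
      }
      if (spec$orientation == "direct") {
        force_diff(mol1, s1[1] - 1L, mol2, s2[1] - 1L)
        force_diff(mol1, s1[2] + 1L, mol2, s2[2] + 1L)
      } else {
        force_diff(mol1, s1[1] - 1L, mol2, s2[2] + 1L, complemented = TRUE)
        force_diff(mol1, s1[2] + 1L, mol2, s2[1] - 1L, complemented = TRUE)
      }
      rep_truth[[i]] <- tibble(
        repeat_id = rid, length = spec$length,
        molecule1 = mol1, start1 = s1[1], end1 = s1[2],
        molecule2 = mol2, start2 = s2[1], end2 = s2[2],
        orientation = spec$orientation)
    }
  }

  # --- plastid-derived segments (MTPTs) -------------------------------
  mtpt_truth <- list()
  if (!is.null(config$mtpt_specs) && nrow(config$mtpt_specs) > 0) {
    for (i in order(-config$mtpt_specs$length)) {     # place longest first
      spec <- config$mtpt_specs[i, ]
      src <- free_slot("cp", spec$length, what = paste0("mtpt source ", i))
      claim("cp", src[1], src[2])
      seg <- seqs[["cp"]][src[1]:src[2]]
      seg2 <- seg
      # substitutions at interior positions, never within 6 bp of an end,
      # so alignment endpoints stay recoverable
      interior <- 7:(spec$length - 6L)
      if (spec$n_sub > 0) {
        pos <- sample(interior, spec$n_sub)
        for (p in pos) {
          seg2[p] <- sample(setdiff(c("A", "C", "G", "T"), seg2[p]), 1)
        }
      }
      if (spec$n_indel > 0) {
        ipos <- sort(sample(setdiff(interior,
                                    if (spec$n_sub > 0) pos else integer()),
                            spec$n_indel), decreasing = TRUE)
        for (k in seq_along(ipos)) {
          p <- ipos[k]
          if (k %% 2 == 1) {          # deletion of 1 bp
            seg2 <- seg2[-p]
          } else {                    # insertion of 1 bp
            seg2 <- append(seg2, sample(c("A", "C", "G", "T"), 1), after = p)
          }
        }
      }
      mt_mol <- mol_ids[1 + (i - 1) %% n_mt]
      dst <- free_slot(mt_mol, length(seg2), what = paste0("mtpt ", i))
      seqs[[mt_mol]][dst[1]:(dst[1] + length(seg2) - 1L)] <- seg2
      claim(mt_mol, dst[1], dst[1] + length(seg2) - 1L)
      # anti-homologous guard flanks: 15 bp on each side of the source gets
      # an AC-repeat and the insertion a GT-repeat; the motifs share no
      # match at any shift, so a local alignment cannot extend past the
      # planted boundary, gapped or not
      cp_guard <- chars(strrep("AC", 8))[1:15]
      mt_guard <- chars(strrep("GT", 8))[1:15]
      for (k in 1:15) {
        lp <- dst[1] - k; rp <- dst[1] + length(seg2) - 1L + k
        seqs[["cp"]][src[1] - k] <- cp_guard[k]
        seqs[["cp"]][src[2] + k] <- cp_guard[k]
        seqs[[mt_mol]][lp] <- mt_guard[k]
        seqs[[mt_mol]][rp] <- mt_guard[k]
      }
      mtpt_truth[[i]] <- tibble(
        mtpt_id = paste0("p", i), cp_start = src[1], cp_end = src[2],
        mt_molecule = mt_mol, mt_start = dst[1],
        mt_end = dst[1] + length(seg2) - 1L,
        n_sub = spec$n_sub, n_indel = spec$n_indel)
    }
  }

  # --- protein-coding genes -------------------------------------------
  codons <- apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                              c("A", "C", "G", "T")), 1, paste, collapse = "")
  codons <- setdiff(codons, c("TAA", "TAG", "TGA"))
  make_orf <- function(len) {
    n_cod <- max(3L, round(len / 3)) - 2L
    paste0("ATG", paste(sample(codons, n_cod, replace = TRUE),
                        collapse = ""), "TAA")
  }
  feats <- list()
  plant_genes <- function(mols, count, prefix) {
    for (i in seq_len(count)) {
      mol <- if (length(mols) == 1) mols else sample(mols, 1)
      glen <- sample(seq(config$gene_length_range[1],
                         config$gene_length_range[2], by = 3L), 1L)
      orf <- make_orf(glen)
      glen <- nchar(orf)
      slot <- free_slot(mol, glen, what = paste0(prefix, i))
      strand <- sample(c("+", "-"), 1)
      placed <- if (strand == "-") revcomp(orf) else orf
      seqs[[mol]][slot[1]:slot[2]] <<- chars(placed)
      claim(mol, slot[1], slot[2])
      feats[[length(feats) + 1]] <<- tibble(
        gene = paste0(prefix, i), molecule = mol, start = slot[1],
        end = slot[2], strand = strand, type = "PCG",
        exons = list(tibble(start = slot[1], end = slot[2])))
    }
  }
  plant_genes(mol_ids[seq_len(n_mt)], config$n_genes_mt, "mtg")
  plant_genes("cp", config$n_genes_cp, "cpg")

  molecules <- molecule_table(
    id = mol_ids,
    sequence = vapply(seqs, paste, character(1), collapse = ""),
    topology = topo, organelle = org)
  features <- dplyr::bind_rows(feats)
  truth <- list(
    repeats = if (length(rep_truth)) dplyr::bind_rows(rep_truth) else
      tibble(repeat_id = character()),
    mtpts = if (length(mtpt_truth)) dplyr::bind_rows(mtpt_truth) else
      tibble(mtpt_id = character()),
    mixture = config$conformation_mixture)
  list(molecules = molecules, features = features, truth = truth)
}
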