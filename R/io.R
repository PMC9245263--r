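#' Construct a genome molecule table
#'
#' The package represents genomes as a tibble with one row per molecule:
#' `id`, `sequence` (uppercase ACGTN), `topology` (`"circular"` or
#' `"linear"`) and `organelle` (`"mito"` or `"plastid"`). A `length`
#' column is derived.
#'
#' @param id character vector of molecule names.
#' @param sequence character vector of DNA sequences.
#' @param topology `"circular"` or `"linear"`, recycled.
#' @param organelle `"mito"` or `"plastid"`, recycled.
#' @return a tibble of molecules.
#' @export
molecule_table <- function(id, sequence, topology = "linear",
                           organelle = "mito") {
  stopifnot(length(id) == length(sequence), all(nchar(sequence) > 0))
  topology <- rep_len(topology, length(id))
  organelle <- rep_len(organelle, length(id))
  stopifnot(all(topology %in% c("circular", "linear")),
            all(organelle %in% c("mito", "plastid")))
  sequence <- toupper(sequence)
  bad <- grepl("[^ACGTN]", sequence)
  if (any(bad)) stop("non-ACGTN characters in molecule(s): ",
                     paste(id[bad], collapse = ", "))
  tibble(id = as.character(id), sequence = sequence,
         length = nchar(sequence), topology = topology,
         organelle = organelle)
}

#' Read and write genome FASTA
#'
#' Thin wrappers around [Biostrings::readDNAStringSet()] /
#' [Biostrings::writeXStringSet()]. The writer stores `topology=` and
#' `organelle=` key-value pairs in the description line; the reader
#' recovers them when present (defaults: linear, mito). Lowercase input
#' is normalised to uppercase with a message.
#'
#' @param path file path.
#' @param molecules a molecule tibble (see [molecule_table()]).
#' @return `read_fasta()` returns a molecule tibble; `write_fasta()`
#'   returns `path` invisibly.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  if (length(x) == 0) stop("no FASTA records in ", path)
  hdr <- names(x)
  id <- sub("\\s.*$", "", hdr)
  get_kv <- function(key, default) {
    m <- stringr::str_match(hdr, paste0(key, "=(\\S+)"))[, 2]
    ifelse(is.na(m), default, m)
  }
  seqs <- unname(as.character(x))
  if (any(grepl("[acgtn]", seqs))) {
    message("lowercase bases normalised to uppercase")
  }
  molecule_table(id, toupper(seqs),
                 topology = get_kv("topology", "linear"),
                 organelle = get_kv("organelle", "mito"))
}

#' @rdname read_fasta
#' @export
write_fasta <- function(molecules, path) {
  x <- Biostrings::DNAStringSet(molecules$sequence)
  names(x) <- sprintf("%s topology=%s organelle=%s", molecules$id,
                      molecules$topology, molecules$organelle)
  Biostrings::writeXStringSet(x, path, width = 70)
  invisible(path)
}

#' Write reads as FASTQ with placeholder qualities
#'
#' Base qualities carry no information in this pipeline; a constant
#' quality (`"I"`, Phred 40) is written.
#'
#' @param reads tibble with columns `read_id`, `sequence`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  x <- Biostrings::DNAStringSet(reads$sequence)
  names(x) <- reads$read_id
  q <- Biostrings::BStringSet(vapply(nchar(reads$sequence),
                                     function(n) strrep("I", n), character(1)))
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = q)
  invisible(path)
}

#' Read a FASTA/FASTQ read file into a read tibble
#'
#' @param path file path.
#' @param format `"fasta"` or `"fastq"`.
#' @return tibble with `read_id`, `sequence`.
#' @export
read_reads <- function(path, format = c("fasta", "fastq")) {
  format <- match.arg(format)
  x <- Biostrings::readDNAStringSet(path, format = format)
  tibble(read_id = sub("\\s.*$", "", names(x)),
         sequence = unname(toupper(as.character(x))))
}

#' Read gene features from GFF3
#'
#' Parses `gene`/`CDS`/`exon` records via `rtracklayer::import()` into the
#' package's feature tibble: one row per gene with columns `gene`,
#' `molecule`, `start`, `end` (1-based inclusive, ascending), `strand`,
#' `type`, and a list column `exons` of per-exon `start`/`end` tibbles
#' (ordered along the molecule). Genes without explicit CDS/exon children
#' get a single exon spanning the gene.
#'
#' @param path GFF3 path.
#' @return feature tibble.
#' @export
read_gff3 <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    stop("rtracklayer is required to read GFF3")
  }
  g <- rtracklayer::import(path, format = "gff3")
  d <- as_tibble(as.data.frame(g))
  d$seqnames <- as.character(d$seqnames)
  d$strand <- as.character(d$strand)
  genes <- d[d$type %in% c("gene", "tRNA", "rRNA"), , drop = FALSE]
  parts <- d[d$type %in% c("CDS", "exon"), , drop = FALSE]
  if (nrow(genes) == 0) stop("no gene records in ", path)
  gid <- if ("ID" %in% names(genes)) genes$ID else genes$Name
  name <- if ("Name" %in% names(genes)) {
    ifelse(is.na(genes$Name), gid, genes$Name)
  } else gid
  ftype <- if ("feature_class" %in% names(genes)) {
    genes$feature_class
  } else ifelse(genes$type == "gene", "PCG", as.character(genes$type))
  exons <- lapply(seq_len(nrow(genes)), function(i) {
    par <- character(0)
    if (nrow(parts) > 0 && "Parent" %in% names(parts)) {
      keep <- vapply(parts$Parent, function(p) gid[i] %in% as.character(p),
                     logical(1))
      px <- parts[keep, , drop = FALSE]
      # prefer CDS records when both are present
      if (any(px$type == "CDS")) px <- px[px$type == "CDS", , drop = FALSE]
      if (nrow(px) > 0) {
        px <- px[order(px$start), ]
        return(tibble(start = px$start, end = px$end))
      }
    }
    tibble(start = genes$start[i], end = genes$end[i])
  })
  tibble(gene = as.character(name), molecule = genes$seqnames,
         start = genes$start, end = genes$end, strand = genes$strand,
         type = as.character(ftype), exons = exons)
}

#' @rdname read_gff3
#' @param features feature tibble.
#' @export
write_gff3 <- function(features, path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    stop("rtracklayer is required to write GFF3")
  }
  rows <- purrr::pmap(features, function(gene, molecule, start, end, strand,
                                         type, exons, ...) {
    g <- data.frame(seqnames = molecule, start = start, end = end,
                    strand = strand, type = "gene", ID = gene, Name = gene,
                    feature_class = type)
    widths <- exons$end - exons$start + 1L
    prior <- c(0L, cumsum(widths))[seq_len(nrow(exons))]
    phase <- as.integer((3L - prior %% 3L) %% 3L)
    if (strand == "-") phase <- rev(phase)
    ex <- data.frame(seqnames = molecule, start = exons$start,
                     end = exons$end, strand = strand, type = "CDS",
                     phase = phase,
                     ID = paste0(gene, ".cds", seq_len(nrow(exons))),
                     Name = gene, feature_class = type, Parent = gene)
    dplyr::bind_rows(g, ex)
  })
  d <- dplyr::bind_rows(rows)
  gr <- GenomicRanges::makeGRangesFromDataFrame(d, keep.extra.columns = TRUE)
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Extract spliced coding sequences
#'
#' Joins the exons of each feature in molecule order and reverse
#' complements minus-strand genes, yielding the sense-strand spliced CDS
#' used for read mapping and editing calls.
#'
#' @param molecules molecule tibble.
#' @param features feature tibble (see [read_gff3()]).
#' @return tibble with `gene`, `molecule`, `organelle`, `strand`,
#'   `sequence`, `length`.
#' @export
extract_cds <- function(molecules, features) {
  seqs <- setNames(molecules$sequence, molecules$id)
  orgs <- setNames(molecules$organelle, molecules$id)
  topo <- setNames(molecules$topology, molecules$id)
  out <- purrr::pmap(features, function(gene, molecule, start, end, strand,
                                        type, exons, ...) {
    pieces <- vapply(seq_len(nrow(exons)), function(i) {
      as.character(mol_substr(seqs[[molecule]], exons$start[i], exons$end[i],
                              topo[[molecule]]))
    }, character(1))
    s <- paste(pieces, collapse = "")
    if (strand == "-") s <- revcomp(s)
    tibble(gene = gene, molecule = molecule,
           organelle = unname(orgs[[molecule]]), strand = strand,
           sequence = s, length = nchar(s))
  })
  dplyr::bind_rows(out)
}

#' Read alignments from a SAM file
#'
#' Optional input path for the editing module: a plain-text SAM file is
#' converted to BAM with [Rsamtools::asBam()] and the per-position base
#' composition against its reference sequences is computed with
#' [Rsamtools::pileup()], giving columns directly comparable to
#' [pileup_cds()] output (reference names must be gene ids).
#'
#' @param sam_path path to a SAM file with header.
#' @param cds tibble from [extract_cds()] providing `gene` and `sequence`
#'   for reference bases.
#' @return pileup tibble (`gene`, `cds_pos`, `ref_base`, `A`, `C`, `G`,
#'   `T`, `depth`).
#' @export
pileup_from_sam <- function(sam_path, cds) {
  if (!requireNamespace("Rsamtools", quietly = TRUE)) {
    stop("Rsamtools is required to read SAM input")
  }
  bam <- Rsamtools::asBam(sam_path, tempfile(), overwrite = TRUE,
                          indexDestination = TRUE)
  p <- Rsamtools::pileup(
    bam,
    pileupParam = Rsamtools::PileupParam(
      max_depth = 100000L, min_base_quality = 0L, min_mapq = 0L,
      distinguish_strands = FALSE, include_insertions = FALSE))
  p <- as_tibble(p)
  p$seqnames <- as.character(p$seqnames)
  p$nucleotide <- as.character(p$nucleotide)
  p <- p[p$nucleotide %in% c("A", "C", "G", "T"), , drop = FALSE]
  wide <- tidyr::pivot_wider(p[, c("seqnames", "pos", "nucleotide", "count")],
                             names_from = "nucleotide",
                             values_from = "count", values_fill = 0L)
  for (b in c("A", "C", "G", "T")) if (!b %in% names(wide)) wide[[b]] <- 0L
  ref <- setNames(cds$sequence, cds$gene)
  wide <- wide[wide$seqnames %in% names(ref), , drop = FALSE]
  tibble(gene = wide$seqnames, cds_pos = as.integer(wide$pos),
         ref_base = substr(ref[wide$seqnames], wide$pos, wide$pos),
         A = as.integer(wide$A), C = as.integer(wide$C),
         G = as.integer(wide$G), T = as.integer(wide$T)) |>
    mutate(depth = .data$A + .data$C + .data$G + .data$T) |>
    arrange(.data$gene, .data$cds_pos)
}
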