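Package: organellr
Title: Repeat-Mediated Recombination, Plastid-Derived Segments and RNA
    Editing in Plant Organelle Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for studying the structural and post-transcriptional
    dynamics of plant organelle genomes from long and short reads.
    Discovers direct and inverted repeats in multipartite mitochondrial
    genomes, builds the four local conformations (two major, two
    crossover) around each repeat, classifies fully spanning long reads
    and estimates recombination frequencies; detects plastid-derived
    segments (MTPTs) in mitochondrial DNA with a seed-and-extend local
    aligner using BLASTn-style scoring and E-values, and verifies their
    integration with spanning long reads; calls RNA-editing sites in
    organelle protein-coding genes from read pileups with
    organelle-specific coverage thresholds and DNA-level SNP exclusion.
    A seeded simulator generates organelle genome pairs with planted
    repeats, transferred segments, conformation mixtures, editing sites
    and SNPs, plus error-bearing long, RNA-seq and WGS reads, so the
    whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    GenomicRanges,
    Rsamtools,
    rtracklayer,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
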