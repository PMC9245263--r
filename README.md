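# organellr

Plant mitochondrial genomes recombine across repeated sequences, so one
plant carries a mixture of genome conformations; they also absorb
stretches of chloroplast DNA (MTPTs — mitochondrial plastid DNA), and
their coding transcripts are post-transcriptionally edited, mostly
C-to-U. `organellr` is an R package for quantifying all three phenomena
from sequencing reads, written for organelle-genomics analysts who have
assembled mitochondrial + plastid genomes and long-read / RNA-seq / WGS
data in hand.

## What it computes

**Repeat-mediated recombination.** For each repeat pair (copies A, B)
four local reference paths are built, each `flank + repeat + flank`
(flank 1 kb by default):

```
m1 = A_up · R · A_down     m2 = B_up · R · B_down     (major, as assembled)
s1 = A_up · R · B_down     s2 = B_up · R · A_down     (crossover products)
```

A long read supports a path only if it covers the *entire* path —
repeat plus both full flanks — at identity ≥ 0.85. Support is counted
with the max rule `n_major = max(#m1, #m2)`, `n_alternative = max(#s1,
#s2)` (the two paths of one conformation describe the same molecule),
and reported as percentages rounded half-up to two decimals:
`pct = 100 · n / (n_major + n_alternative)`.

**MTPT detection.** A self-contained seed-and-extend local aligner
(exact 9-mer seeds, +2/−3, gap `5 + 2k`, E ≤ 1e-5 with gapped
Karlin–Altschul constants λ = 0.625, K = 0.41, no dust masking) aligns
plastid against mitochondrial molecules, merges subsumed alignments,
bins hits by identity (100% / 90–100% / 80–90% / <80%), annotates
contained plastid genes (`-fra` marks fragments), and summarises
genome coverage as the union of hit intervals. Integration is verified
by long reads spanning the segment plus flanking mitochondrial
sequence on both sides.

**RNA editing.** Reads are piled up against spliced coding sequences;
a site is called at ≥ 20× (plastid) or ≥ 10× (mitochondrial) depth when
the top non-reference base reaches 10% support and the position is not
a DNA SNP called from WGS reads under the same thresholds. Efficiency
is edited reads over total depth; summaries count the 12 edit types and
bin efficiencies.

A fully seeded simulator (`sim_config()`, `simulate_genomes()`,
`simulate_long_reads()`, `simulate_spanning_reads()`,
`simulate_rnaseq_wgs()`) generates genomes with planted repeats,
transferred segments, conformation mixtures, editing sites and SNPs,
plus error-bearing reads, so the whole pipeline runs and is tested
without any external download.

## Worked example

```r
library(organellr)

cfg <- sim_config(
  seed = 42,
  mt_lengths = c(30000, 20000), cp_length = 12000,
  repeat_specs = tibble::tibble(length = 800, orientation = "direct",
                                placement = "intra"),
  mtpt_specs = tibble::tibble(length = 1500, n_sub = 5, n_indel = 0),
  conformation_mixture = c(R1 = 0.3))
sim <- simulate_genomes(cfg)

classify_repeats(find_repeats(sim$molecules, min_len = 100))
#>   repeat_id klass length molecule1 start1  end1 start2  end2 orientation
#> 1 SR1       short    800 mt1        23996 24795  28826 29625 forward

rp <- sim$truth$repeats[1, ]
reads <- simulate_spanning_reads(sim$molecules, rp, n = 300,
                                 alt_fraction = 0.3, seed = 42)
cs <- build_conformations(sim$molecules, rp)
quantify_recombination(classify_spanning_reads(reads$reads, cs))
#>   repeat_id n_major n_alternative n_ambiguous pct_major pct_alternative active
#> 1 R1            200           100           0      66.7            33.3 TRUE
```

Of 300 error-free reads spanning the repeat plus both 1 kb flanks, 200
support the assembled arrangement and 100 the crossover (the stored
percentages are 66.67 / 33.33; the tibble display trims a digit) —
recovering the planted 30% alternative-conformation fraction; the
repeat is recombinationally active.

```r
cp <- sim$molecules[sim$molecules$organelle == "plastid", ]
mt <- sim$molecules[sim$molecules$organelle == "mito", ]
find_mtpts(cp, mt)
#>   id    aligned_length mt_molecule mt_start mt_end cp_start cp_end identity n_mismatches similarity_class
#> 1 mtpt1           1500 mt1              809   2308     9507  11006    0.997            5 ge90lt100
```

The planted 1.5 kb plastid-derived segment is found as a single hit at
its exact coordinates with exactly the 5 planted mismatches, in the
90–100% similarity class.

```r
cds <- extract_cds(sim$molecules, sim$features)
specs <- plant_site_specs(cds, n_sites = 30, n_snps = 3, seed = 42)
rw <- simulate_rnaseq_wgs(cds, specs$editing_specs, specs$snp_specs,
                          depth = 50, seed = 42)
org <- setNames(cds$organelle, cds$gene)
snps <- call_snps(pileup_cds(rw$wgs_reads, cds), org)
sites <- call_editing_sites(pileup_cds(rw$rna_reads, cds), snps, org)
summarize_editing(sites)
#> <editing_summary> 30 sites; 16.67 % above 0.9 efficiency
#>   most common type: C to U ( 21 )
```

All 30 planted editing sites are recovered (C-to-U dominating, as
planted), none of the 3 DNA SNPs leaks into the editing calls, and
16.67% of sites exceed 90% efficiency.

`run_pipeline(cfg, out_dir)` chains all stages and writes the repeat,
recombination, MTPT and editing tables as TSV plus a JSON run report
that is byte-identical across reruns with the same seed. `tidy()`,
`glance()` and `autoplot()`/`plot_*()` methods cover the result
objects.

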