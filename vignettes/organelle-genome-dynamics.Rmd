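---
title: "Methods: repeat-mediated recombination, plastid-derived segments and RNA editing in organelle genomes"
author: "organellr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: organelle genome dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The biological problem

Plant mitochondrial genomes are structurally dynamic: pairs of repeated
sequences (from ~100 bp to >15 kb) mediate homologous recombination, so a
single plant carries a population of genome conformations rather than one
circle. The same genomes also accumulate DNA of plastid origin (MTPTs,
mitochondrial plastid DNA), and their protein-coding transcripts are
post-transcriptionally edited, predominantly C-to-U. `organellr`
implements the three read-based analyses that quantify these phenomena —
conformation frequencies from long reads, MTPT detection and
verification, and RNA-editing calling — together with a seeded simulator
so every stage is testable without external data.

## Conformation model and spanning-read classification

For a repeat with copies A and B (B possibly inverted), four local
reference paths are built, each `flank + repeat + flank` long:

* `m1 = A_up · R · A_down` and `m2 = B_up · R · B_down` reproduce the
  assembled (major) genome;
* `s1 = A_up · R · B_down` and `s2 = B_up · R · A_down` are the two
  crossover (alternative) products.

For an inverted copy B, its flanks enter the paths reverse-complemented
so each path is a valid linear sequence. The flank defaults to 1000 bp —
long enough that a read covering a full path cannot be placed by the
repeat alone. Circular molecules supply wrap-around flanks; at a linear
molecule end, a truncated flank is recorded in the provenance so the
user can exclude the repeat.

Each long read (or its reverse complement, chosen by k-mer diagonal
voting) is aligned to each path with a banded affine-gap alignment in
which the path is global and the read's overhangs are free. A path is
*supported* only when the alignment covers the whole path — no terminal
path clipping — at identity at or above `min_identity` (default 0.85,
chosen to admit reads at typical Nanopore error while rejecting
cross-conformation mismaps; configurable). A read supporting only
m-paths is `major`, only s-paths `alternative`. The mapping literature
behind this analysis does not pin down how undecidable reads were
curated away, so we adopt an explicit rule: a read whose best m-path and
best s-path identities differ by less than `ambiguity_margin` (default
0.02) is `ambiguous` and excluded from both counts and from percentage
denominators.

Counting follows the max-of-same-conformation-paths rule: `n_major =
max(#m1, #m2)` and `n_alternative = max(#s1, #s2)`, because the two
paths of one conformation describe the same molecule seen from the two
repeat copies and double-counting would inflate support. Percentages are
`100 · n / (n_major + n_alternative)` rounded half-up to two decimals,
the convention of the published support tables; `quantify_recombination()`
reports a repeat as recombinationally active when at least one read
supports a crossover path.

## Repeat discovery

Exact maximal repeats are found by anchoring on shared k-mers
(`k = min(21, min_len)`), merging co-diagonal seed runs, and extending
each run maximally; nested sub-pairs therefore never appear. Inverted
repeats are found by the same procedure against the reverse complement;
circular molecules are doubled and hits lying entirely in the second
copy discarded. `min_len` defaults to 100 bp: the shortest repeat with
measurable recombination activity in the motivating dataset is 125 bp,
and 100 bp gives margin without flooding the output. Detection is
exact-match by default because catalogued recombination-active repeats
behave as exact units; a near-exact mode (identity >= 0.9 through the
local aligner) exists because diverged repeats are known to recombine in
some lineages, but it is not the default. Ids are assigned by length
rank within the long/short classes (`LR`/`SR`, threshold 1000 bp), ties
broken by (molecule, start) so output is deterministic.

## MTPT detection: seed-and-extend local alignment

The plastid genome is compared against each mitochondrial molecule with
a self-contained seed-and-extend aligner using the scoring scheme
standard for this analysis: exact 9-mer seeds on both strands, match +2,
mismatch −3, gap open 5, gap extend 2 (a length-k gap costs `5 + 2k`,
the first gap column included — stated explicitly to avoid affine-gap
dialect drift), E-value cutoff 1e-5, and no low-complexity masking.
Seeds are grouped by diagonal, X-drop extended without gaps (X = 20),
and surviving HSPs are polished by a banded local dynamic programme over
a window padded by 3000 bp (band half-width 64). E-values use
`E = K·m·n·e^(−λS)` with the published gapped Karlin–Altschul constants
for this scheme (λ = 0.625, K = 0.41) and m, n the full genome lengths;
the constants are parameters of `alignment_params()` so thresholding is
reproducible. Lower-scoring alignments whose query and subject intervals
are both at least half-covered by a higher-scoring hit are treated as
subsumed duplicates and dropped; hit counts are therefore
"after merging", one of the two defensible conventions.

Because a local alignment ends wherever its score is maximal, a planted
segment may gain a few chance-matching flank bases at either end; tests
therefore require endpoint agreement within ±5 bp rather than exact.

Hits are ordered by aligned length (`mtpt1`, `mtpt2`, ...), binned by
identity into the similarity classes used for display (100%, 90–100%,
80–90%, <80%), and annotated with contained plastid genes: a gene whose
full annotated span lies inside the hit is complete, a partially
overlapping gene is a fragment (`-fra`). The direction of transfer is
deliberately not inferred — for several tRNA loci it is undecidable —
so hits carry a neutral "homologous segment" semantic. Genome coverage
is summarised as the union of hit intervals (overlaps counted once, via
`IRanges::reduce()`); raw summed lengths are reported alongside because
duplicated regions (e.g. plastid IRs) make the conventions differ, and
the published totals do not say which was used.

Integration of an MTPT into the mitochondrial genome is verified by long
reads: at least one read must cover the entire segment plus at least
`flank` bp of mitochondrial sequence on both sides — reads wholly of
plastid origin can never satisfy this.

## RNA-editing calling

Reads are mapped to spliced coding sequences (exons joined, sense
strand), so "C to U" means a sense-strand C→T difference in RNA reads.
Per-column base composition is tallied from the alignment; insertion
columns in the read are skipped and read deletions contribute no count.
A site is called when depth reaches the organelle-specific floor (20x
plastid, 10x mitochondrial — low-copy, often lowly expressed), the most
frequent non-reference base reaches 10% support, and the position is not
a DNA SNP called from WGS reads under the same thresholds. Efficiency is
the edited-base count divided by *total* depth (all four bases), so
sequencing-error bases correctly depress it. The edited base is the
argmax non-reference base; multi-allelic ties are flagged ambiguous and
excluded from type totals rather than guessed. Replicate transcriptome
runs are pooled into one pileup by default (how replicates were combined
is not stated in the motivating analysis; pooling is the conservative
reading of a single support threshold), with per-replicate calling
available by running the caller per read set. Genes with inadequate
coverage simply fail the depth floor; no imputation is attempted.

The summary counts sites per gene and per the 12 ordered edit types, and
bins efficiencies into [0, 0.5), [0.5, 0.8), [0.8, 0.9), [0.9, 1] — the
display bins are not formally defined in the source material, so these
are declared and configurable in spirit (the bin edges live in one
place). "Above 90%" is strict (> 0.9), so a site at exactly 0.9 falls in
the top histogram bin but not in the >90% fraction.

## The simulator: what it emulates, and what it does not

`sim_config()` + `simulate_genomes()` build a bipartite mitochondrial
genome and a plastid genome with planted truth. Design choices:

* Background sequence is i.i.d. per-base at the configured GC fraction
  (default 0.45) — the simplest null that still exercises E-value
  thresholds.
* Planted repeats are exact copies with boundary guard bases forced to
  mismatch, so the planted coordinates *are* the maximal repeat and
  coordinate-exact recovery is well-defined.
* MTPT specs plant exactly the requested substitution and 1-bp indel
  counts, at interior positions (>= 7 bp from the ends) so alignment
  endpoints remain recoverable. Each planted boundary is flanked by
  15 bp anti-homologous guard motifs (an AC-repeat on the plastid side,
  a GT-repeat on the mitochondrial side — zero matches at any shift):
  without them, a maximal-scoring local alignment occasionally extends
  past the planted boundary through chance flank homology (random
  flanks contain lucky near-exact stretches, and complementary or
  AT-rich flanks are quasi-self-similar under small shifts), which
  would make "the planted interval" ill-defined as an alignment truth.
* Structural elements are placed longest-first into explicitly
  enumerated free gaps, so any configuration that fits is placed
  deterministically rather than by rejection sampling.
* Genes are simple ORFs (ATG, no internal stop, TAA, length divisible
  by 3), single-exon by default.
* Long-read lengths are log-normal truncated to [200 bp, molecule
  length] — a Nanopore-like heavy tail at desk scale; reads come from
  both strands with probability 0.5 and cross the origin of circular
  molecules. Default error rates (5% substitution, 1.5% + 1.5% indel)
  are placeholders — the motivating dataset reports only an N50 — and
  fully configurable.
* Spanning-read simulation draws each read from the crossover
  conformation with the planted probability. By default reads are
  anchored at the first repeat copy (major reads show the m1 junction,
  alternative reads s1), giving the frequency estimator its nominal
  Binomial(n, f) sampling distribution; a `"both"` mode samples
  junctions uniformly within each class, which halves the effective
  count through the max rule and is the genome-wide sampling picture.
* RNA reads are simulated from spliced CDS, not genomic context,
  matching the mapping target of the editing analysis. The default
  editing model plants `round(efficiency × covering reads)` edited reads
  per site ("exact" mode) so that planted truth is recoverable at the
  stated efficiency; a `"binomial"` mode draws each read independently
  for studies of calling variance. SNPs are fixed differences present in
  both WGS and RNA reads.
* FASTQ qualities are constant placeholders; no stage uses base quality.

Not emulated: chimeric/adapter artifacts, quality-score structure,
context-dependent error, expression-level variation between genes, and
real flow-cell signal. Passing tests on this simulator therefore
demonstrate algorithmic correctness under a clean error model, not
robustness to every artefact of real libraries.

## Numerical choices and degenerate inputs

* Percent rounding is half-up at two decimals (`round_half_up()`), with
  a small epsilon guarding against floating-point representation of
  values like 100 × 173/190.
* Alignment bands scale with path length (12%, floor 50 columns) for
  spanning classification and are fixed (64) for the homology gapped
  stage; the k-mer diagonal vote buckets offsets at width 16, so band
  widths comfortably absorb the <=16 bp anchoring error plus indel
  drift. A read whose true alignment leaves the band simply fails to
  span — conservative for support counting.
* Zero support: percentages are reported `NA`, the repeat inactive.
* Repeat copies closer than twice the flank trigger a warning (crossover
  paths would overlap the opposite copy); flank truncation at linear
  ends is recorded in path provenance.
* Ties everywhere (repeat ids, read-to-CDS assignment, best path) break
  deterministically toward the lexicographically/coordinate-first
  option and are flagged where scientifically meaningful.

## Problem sizes

The bundled tests and the acceptance script run the pipeline at desk
scale, chosen as the package's own study conditions: mitochondrial
molecules of 20–40 kb with repeats of 0.25–2 kb, a 15 kb plastid
molecule, planted MTPTs of 60 bp–5.1 kb at 85–100% identity, 1000
spanning reads per mixture fraction, and 20 coding genes at 50x depth
with 200 planted editing sites and 10 SNPs. These reproduce every
structural feature of the motivating dataset (multi-molecule mtDNA,
direct/inverted and intra-/inter-molecular repeats, IR-style duplicated
hits, C-to-U-dominated editing) at roughly one-tenth genomic scale.

## Known limitations

* The exact-repeat finder reports identity-1 pairs only; diverged
  repeat families require the near-exact mode, whose boundary precision
  is alignment-limited.
* The aligner is seed-and-extend: homology with no exact `word_size`
  seed on the optimal alignment is invisible, exactly as for the tool
  it mirrors.
* Conformation quantification assumes the four-path local model; it does
  not reconstruct the full population of subgenomic molecules, nor does
  it model three-copy repeats jointly (each pair is analysed
  independently).
* E-value constants are the published gapped Karlin–Altschul values for
  the +2/−3, 5/2 scheme, not recomputed from islands statistics.
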