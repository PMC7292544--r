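---
title: "Methods: capture design and quantification in quantcap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: capture design and quantification in quantcap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(quantcap)
library(dplyr)
```

`quantcap` covers the computational halves of a targeted sequence-capture
experiment: designing a tiled probe ("bait") library for a chosen gene
set, and turning the resulting capture-seq alignments into normalized,
clustered expression profiles. This vignette documents the models and
procedures, the parameters that matter, the numerical conventions, and
what the synthetic-data generator does and does not emulate.

## Capture templates

For each target gene the capture window is *promoter + gene body +
terminator*, built from a GFF3 annotation:

* **Coordinates.** Internally everything is 0-based half-open; GFF3 is
  read as 1-based inclusive and BED is written 0-based half-open, the
  native convention of each format.
* **Flank rule.** The upstream (promoter) and downstream (terminator)
  flank lengths are the intergenic gaps measured from the target gene's
  CDS boundaries to the CDS of the nearest neighbouring gene on either
  strand, capped at `flank_cap = 4500` bp. An isolated gene therefore
  gets 4,500 bp on each side; a gene 1,000 bp from its neighbour's CDS
  gets 1,000 bp. The cap reflects how far regulatory sequence is
  plausibly worth capturing; measuring CDS-to-CDS (rather than
  gene-to-gene) lets annotated UTRs be absorbed into the flank. Where an
  annotation distinguishes UTRs, the window is additionally forced to
  contain the whole gene, and the recorded promoter/terminator lengths
  are the extents beyond the gene boundaries — for the common case of
  CDS-spanning gene models the two definitions coincide. Whether the cap
  should be anchored at the start/stop codon or at the transcript
  boundary is genuinely open; the CDS anchoring is used and flagged here
  for users with UTR-rich annotations.
* **Orientation.** "Upstream" is resolved in transcription orientation:
  the promoter of a minus-strand gene lies genomically right of it, and
  all templates are emitted on the coding strand (minus-strand windows
  are reverse-complemented).
* **Degenerate annotation.** A gene without CDS features uses its gene
  boundaries as CDS proxy (with a warning); a neighbour whose CDS
  overlaps the target CDS clamps the flank to zero rather than going
  negative; windows are clipped at chromosome ends. One window is built
  per gene ID (the exon union across isoforms); isoform selection is out
  of scope.

## Bait tiling and filtering

Probes are fixed-length (`bait_len = 120` nt, the standard length of
synthesized biotinylated RNA capture probes) tiled with `overlap = 17`
nt, i.e. step 103 nt. Repeat intervals are subtracted *before* tiling
(`mask_policy = "exclude"`), so masked stretches break the tiling frame
and each unmasked sub-interval is tiled independently: probes start at
offsets 0, 103, 206, … and, whenever the regular frame would leave a
tail uncovered, a final probe is end-anchored at `L - 120`. This
guarantees complete coverage of every unmasked stretch of at least one
probe length — the property that makes 100% breadth of coverage
attainable in a capture — at the cost of the final probe overlapping its
predecessor by more than 17 nt. Sub-intervals shorter than 120 nt yield
no probe (fixed-length chemistry) and are reported per gene.

Pooled probes are deduplicated — two adjacent target genes share their
intergenic span, and identical (chromosome, interval) pairs or identical
sequences are emitted once, the first in (chromosome, start, gene) order
winning deterministically.

**Specificity.** A probe is removed when its sequence occurs more than
`max_hits = 10` times in the genome. Occurrences are counted as exact
matches on both strands, overlapping occurrences counted separately (a
palindromic probe at one locus counts twice); probes containing IUPAC
ambiguity codes are matched with those positions as wildcards. The
strict inequality matters: a 10-copy probe is kept, an 11-copy probe is
removed. Exact-match counting is a deliberately conservative,
dependency-free proxy for alignment-based hit counting (e.g. MEGABLAST):
for 120-mers an exact repeat is the dominant failure mode of capture
specificity, but the two counts are not equivalent — an external
aligner's hit table can be substituted via the `hit_count` column before
filtering.

## Quantification

Reads are assigned to a region when their alignment span overlaps it by
at least 1 bp; only primary, mapped, non-supplementary alignments count,
and a read counts once in every region it touches (regions never overlap
by construction, but adjacency and shared flanks are possible). Breadth
of coverage — the fraction of region positions with depth ≥ 1 — uses the
full reference span of spliced reads, because it asks "did the baits
pull this locus down"; mean depth uses the aligned blocks, because it
quantifies sequence yield. Duplicate reads are *not* removed: tagmented
libraries carry no UMIs and duplicate removal would bias high-expression
loci. SAM input is converted and coordinate-sorted internally;
unsorted BAM input is a hard error rather than a silent resort.

Genomic-DNA spike-in libraries travel through the same counting code but
land only in the coverage report: every locus exists in gDNA, so a
correctly working capture gives breadth 1.0 on every region, making the
spike-ins a positive control for bait function. Symmetrically, a
designated negative-control region — a locus not expressed in the
sampled tissue — must collect zero cDNA reads; any read there flags
library contamination.

## Normalization and profiles

Counts are normalized on control genes in two steps:

1. **Goodness of fit.** Each candidate control is scored by the Pearson
   chi-square of its counts against expectations proportional to library
   size, `X² = Σ_j (O_j − E_j)²/E_j` with `E_j = rowSum·libSize_j /
   ΣlibSize`. The statistic is 0 exactly when the gene tracks library
   size perfectly and grows with biological or technical instability,
   so candidates are ranked ascending and the `k` lowest (or all below a
   threshold) are kept; scores, ranking and selection are all surfaced
   for audit. The expectation is computed as `outer(rowSum, libSize) /
   ΣlibSize` — one division — so a perfectly proportional row scores
   exactly 0 in floating point, not merely near it.
2. **Median-of-ratios scaling.** Per selected control, a reference level
   is its geometric mean across samples (zeros excluded); a sample's
   scale factor is the median over controls of `count/reference`,
   rescaled to geometric mean 1. This is the standard robust size-factor
   estimator restricted to a trusted gene set: with a minority of
   misbehaving controls the median ignores them, and if the controls are
   true nulls the planted factors are recovered exactly at zero noise.
   Renormalizing an already-normalized matrix yields factors of 1
   (idempotence), which the test suite asserts to 1e-8.

Condition profiles are per-gene `log2((mean_cond + pc)/(mean_ref +
pc))`, replicate means within each `genotype_treatment` condition
against the reference condition (`wt_un` by default). The pseudocount
`pc = 1` guards zeros at the cost of shrinking ratios of
low-expression genes; the shrinkage is deterministic and accounted for
in the recovery tests ("pseudocount-adjusted" truth). Row z-scores use
the sample standard deviation (n−1); constant rows map to all-zero
z-scores with a warning rather than NaN.

**Clustering.** Genes cluster on correlation distance (1 − Pearson) —
profile shape matters more than amplitude once rows are z-scored —
and conditions on Euclidean distance, both with average linkage, trees
cut at `k_genes = 3` / `k_conditions = 3` by default (matching the
coarse structure expected of an immune-activation panel: induced,
repressed/late, and stable genes; mock-like, strongly-responding and
heterogeneous conditions). Rows with undefined correlation (constant
z-rows) are placed at the maximum correlation distance 2. All
choices are overridable; results are deterministic given inputs and
settings. Differential expression is reported descriptively (log ratios,
z-scores, clusters, correlations) — no per-gene count-model tests and no
multiple-testing machinery, because the intended readout is profile
structure across a designed condition panel, not gene-level discovery.

**Correlation.** Pairwise Pearson/Spearman over samples (reproducibility
of replicates), over conditions, or over genes (`margin = "rows"`).
Zero-variance vectors have undefined correlation and are reported as
`NA` with a warning — notably the reference column of a profile, which
is identically zero and is dropped before condition-level correlation.
Per-gene counts are the correlation basis; correlating per-bin depth
profiles instead is possible upstream but not built in.

## The synthetic-data generator

`simulate_reference()` builds a two-chromosome toy genome (~82 kb)
whose gene layout exercises every geometric branch of the design code:
a chromosome-edge gene, sub-cap (1,000/600/800 bp) and super-cap
(5,000–7,000 bp) intergenic gaps, a minus-strand target, an
overlapping-CDS pair (flank clamped to zero), an adjacent target pair
whose tiling frames coincide in the shared intergenic span (planting
exact duplicate probes), two isolated genes hosting planted multicopy
120-mers — 11 copies (filtered) and 10 copies (kept) — at their capture
window starts, a repeat-masked gene, and a never-expressed
negative-control gene. Gene structure is deterministic; sequence content
is seeded-random.

`simulate_counts()` draws `count ~ NB(mu, dispersion)` with `mu =
libFactor_sample × base_gene × multiplier(gene, condition)`. The default
condition design is the full study layout: 8 genotypes (wild type plus
seven immune-signalling mutants) × 4 treatments (mock, PTI-only
effector, and two PTI+ETI effectors) plus untreated wild type, 3
replicates — 99 cDNA samples — with gDNA spike-ins at the alignment
level. Planted effects follow three structured archetypes chosen to be
nearly orthogonal as condition profiles: *induced* (4–8× under effector
treatments, attenuated in the mutants that disable the corresponding
pathway), *repressed* (0.4× under all effector treatments), and
*genotype-driven* (4× in two mutant backgrounds regardless of
treatment); stable controls sit at multiplier 1 and the negative control
at 0. Baselines are drawn log-uniformly from 100–2000 and rounded to a
resolution of 10 counts, so zero-dispersion runs with dyadic library
factors stay exactly integral — the basis of the exact recovery checks.
At `dispersion = 0` the generator returns the exact real-valued expected
products rather than rounded integers; the integer-count contract
applies to the stochastic path.

`simulate_alignments()` emits per-sample SAM files of 74-nt single-end
reads: cDNA reads uniformly within the expressed gene bodies (one read
per simulated count), gDNA reads tiling every capture window at a 37-nt
step so breadth reaches exactly 1. Reads are written as already-aligned
records — no aligner, no sequencing-error or fragment-length model, no
splicing (intron-containing genes are covered contiguously), all reads
on the forward strand. Passing tests on these fixtures therefore
demonstrates the correctness of the design/counting/normalization
arithmetic, not robustness to alignment artefacts, mapping ambiguity or
real library noise.

## Problem sizes and numerical choices

The test suite and the acceptance script run entirely on generated data,
sized for completeness rather than scale: the ~82 kb two-chromosome
reference with 9 target genes for everything alignment-level (where
brute-force per-base and per-position oracles are feasible), the
99-sample count-level design for normalization, profiling and
clustering, 1,000 random interval lengths for the tiling law, and 20
seeded studies for cluster recovery (adjusted Rand index against the
planted archetypes, computed on the genes carrying planted effects;
flat controls carry none and are excluded from the score, though they
are normalized and clustered like every other gene). Scale-factor
recovery is asserted to 1e-6 and idempotence to 1e-8; exact-zero
assertions (goodness of fit of perfect controls) are arranged to be
exact in floating point as described above; z-score contracts to
1e-10; correlation positive semidefiniteness to −1e-8.

## Limitations

* Specificity is exact-match counting, not alignment-based; divergent
  repeats below 100% identity are invisible to it.
* One capture window per gene ID; no isoform or UTR modelling.
* Probe thermodynamics (Tm, GC, hairpins) and manufacturer panel
  packing are out of scope — the library is sequence-complete, not
  synthesis-optimized.
* Read counting has no duplicate removal and no multi-mapper
  resolution; quantification quality is bounded by the upstream
  aligner.
* The generator's noise model is negative-binomial with a single
  dispersion; it does not emulate capture efficiency differences
  between loci, GC bias, or batch structure.
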