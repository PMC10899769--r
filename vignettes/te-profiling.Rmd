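---
title: "Profiling chromatin signal over transposable elements with teprofiler"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling chromatin signal over transposable elements with teprofiler}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(teprofiler)
```

## The analysis

Transposable elements (TEs) make up roughly half of the human genome.
RepeatMasker-style annotations organize their copies hierarchically —
class (SINE, LINE, LTR, DNA, Satellite, Other/SVA, ...), family (Alu,
L1, ERV1, ...), repeat name (AluYa5, L1HS, SVA_F, ...) — and each repeat
name can be dated by the oldest taxonomic clade in which orthologous
copies are found, from Non-Primates up to *Homo sapiens*.  `teprofiler`
implements a repeat-centric epigenomic profiling pipeline around this
hierarchy:

* **Catalog handling** — parse GTF/BED repeat annotations, drop
  uncertain (`'?'`-suffixed) classifications and blacklist-overlapping
  copies, compute per-group genome occupancy, split labeled genome
  segments (e.g. Hi-C A/B compartments) into repetitive (R) and
  non-repetitive (NR) fractions, and attach clade ranks from a
  user-supplied table.
* **Signal aggregation** — build piecewise-constant coverage from
  alignment spans (unique-only or fractional 1/k multi-map weighting),
  scale to reads per million, subtract input, and summarize the
  resulting signal per repeat copy into an abundance table.
* **Meta-repeat profiles** — scale every copy body to a fixed number of
  bins, add fixed-width flanks, orient by strand, and average; plus
  reference-point profiles, row z-scaling and euclidean/complete
  hierarchical ordering for heatmaps.
* **Peak–repeat enrichment** — assign peaks to copies under a
  ≥ 50%-of-peak-length rule and calibrate per-class enrichment against
  a constrained shuffled null (same chromosome, same lengths, no
  blacklist contact, no mutual overlap).
* **Tandem structure** — classify copies of a focal family as
  alone/first/internal/last relative to same-superfamily neighbors
  within a 500-bp window.
* **Age stratification** — per-clade signal summaries with
  Kruskal–Wallis and one-sample Wilcoxon annotations, and a Spearman
  age-trend statistic.
* **Repeat expression** — per-copy read counting, an expressed split at
  a mean of ≥ 3 reads, a simple two-group count test with
  |FC| > 1.5 / BH-adjusted p < 0.05 classification, group shares of
  up-regulated copies, and read-change categories between conditions.

A seeded synthetic-data generator emulates the statistical structure of
all of these inputs, so the full pipeline is exercised end-to-end
without external data.

## Conventions and containers

All coordinates are 0-based half-open internally; GTF (1-based closed)
is converted at the boundary.  The catalog is a `GRanges` with
`repeat_name`/`family`/`class_name`/`copy_id`/`clade_rank` metadata;
signal lives in per-chromosome run-length encoded vectors (`RleList`),
whose canonical form merges equal-valued adjacent runs.  Occupancy and
the R/NR partition are strand-blind; only meta-profiles honor strand
(5′→3′ orientation, on by default — the 5′/3′ flank semantics imply it,
and it can be disabled).

## Statistical annotations

The rank tests are thin, pure wrappers over the base R machinery:
exact null distributions for small samples without ties, normal
approximations with continuity and tie corrections otherwise.  The test
suite verifies the small-sample signed-rank and Mann–Whitney p-values
against full enumeration of the null (all sign assignments, all group
assignments) up to n = 10.  Spearman correlation matrices are masked at
p < 0.01 by default; constant columns have undefined correlations and
are reported as `NA` with a `FALSE` mask.

## Decisions taken where the design was open

* **Per-copy abundance aggregator.**  The per-repeat summary is the
  length-weighted *mean* of the (input-subtracted) signal — scale-free
  across copy lengths; `sum` and `median` are available
  (`abundance_table(stat =)`).  Group-level heatmaps default to the
  mean of copy means, with median as the configurable alternative.
* **Blacklist rule.**  "Overlapping" is read as ≥ 1 bp and is
  configurable (`apply_exclusions(min_overlap =)`).
* **Peak assignment.**  "Minimum 50%" is inclusive at exactly half.  A
  peak overlapped by several qualifying copies goes to the single copy
  with the largest overlap (ties: leftmost start, then `copy_id`), so
  per-class percentages sum to 100.
* **Shuffled null.**  Preserves chromosome and peak length, not
  inter-peak spacing; peaks are placed in descending length order for
  feasibility.  The null is summarized by mean and SD across shuffles;
  an empirical two-sided rank p-value is reported as supporting
  plumbing.  Because the per-class percentages are shares of assigned
  peaks, they are compositional: genuine enrichment of one class
  necessarily depresses the others' shares.  Interpret depletion
  accordingly, or compare absolute assignment rates.
* **Tandem window.**  The gap is inter-interval distance in genomic
  coordinates (strand ignored; a strand-aware mode is a documented
  alternative), inclusive at exactly 500 bp; overlap counts as distance
  0.  A context copy counts as 5′ when its start lies left of the focal
  start, 3′ when its end lies right of the focal end; a copy nested
  strictly inside the focal copy counts as neither.
* **Clade table.**  Defaults to the seven-label primate lineage
  (Non-Primates … Homo_sapiens); the table is user-supplied so other
  granularities (e.g. an eight-clade split) are expressible.
* **Age trend.**  The clade gradients are usually displayed as ordered
  boxplots; the Spearman rho between clade rank and abundance is an
  added summary statistic for testability, not a display convention.
* **Expression thresholds.**  "Expressed" is a mean of ≥ 3 reads across
  a condition's replicates (inclusive).  Read-change categories use the
  same threshold plus a 1.5-fold pseudocounted (0.5) mean ratio.
  The deregulation call uses the linear-scale |FC| > 1.5 with BH
  p-adjust < 0.05.

## The count test and its calibration

`differential_classification()` is a deliberately simple stand-in for
a shrinkage-based negative-binomial GLM; externally produced
fold-change/p-adjust tables can be classified with `classify_de()`
instead.  The test: total-count library scaling; per-copy
method-of-moments NB dispersion within conditions, pooled, floored at
zero, and *averaged genome-wide* into a common dispersion; then a
two-sided Wald test of the pseudocounted log2 fold change with a
delta-method standard error and normal reference.  Per-copy dispersion
estimates at 2–3 replicates are far too noisy to standardize a Wald
statistic (they make the test anti-conservative), while a common
dispersion calibrates it: the suite checks a type-I error within
[0.03, 0.07] at α = 0.05 on 5000 null copies (mean 50, dispersion 0.1,
3 vs 3) and ≥ 80% detection of planted 4-fold changes.

Copies with a total raw count below `min_total` (default 10) are
excluded before testing; the delta-method approximation is meaningless
at such depths, and excluding them is standard independent filtering.

Total-count scaling has a known composition bias: when derepression is
strong and asymmetric (many copies up, none down), the inflated
knock-down libraries drag unchanged copies toward apparent
down-regulation.  Median-of-ratios normalization would mitigate this;
the simple scaling is kept deliberately and the bias is visible in the
synthetic knock-down fixture.

## The synthetic-data generator

`fixture_spec()` describes a toy genome (default 2 × 1 Mb) carrying
~1900 repeat copies in 14 families across SINE/LINE/LTR/DNA/Other
classes, spanning the seven clades and occupying ~49% of the genome —
about the repetitive fraction of the human genome.  SVA families are
partly placed in tandem clusters (runs of 3 copies with < 500 bp gaps).
Copies are placed uniformly with rejection of overlaps and a minimum
100-bp spacing; blacklist intervals are placed first, in repeat-free
space, so exclusion leaves the planted structure intact.  Signal tracks
are a baseline (1.0) plus multiplicative planted effects per repeat
name — by default an age-graded young-enriched track and its
old-enriched mirror — with linear spillover decay over 500 bp flanks
and gaussian noise drawn per 100-bp window (SD 0.2).  Peaks are the
noise-free super-threshold regions trimmed to enriched copy bodies.
Counts are NB draws (dispersion 0.1, lognormal per-copy means around
50, 30% near-silent copies) with planted 4-fold knock-down effects on
the *Homo sapiens*-restricted names.

What the generator does **not** emulate: sequence content (no FASTA,
no mappability structure), correlated noise or GC bias, per-copy
dispersion heterogeneity beyond the lognormal means, and real
inter-peak spacing.  Passing tests therefore demonstrate algorithmic
correctness and statistical calibration under the planted model, not
robustness to every artifact of real sequencing data.

## Numerical choices

* Body binning uses fractional apportioning (a base overlapping a bin
  edge contributes proportionally), implemented by linear interpolation
  of cumulative sums — exact, and valid for copies shorter than the bin
  count.  Flank bins that extend past a chromosome end are missing
  (`NA`) and excluded from averages, never zero-filled.
* Row z-scaling maps constant rows to zeros and flags them.
  Clustering rows are canonicalized by label before `hclust`, so leaf
  order is invariant to input row permutation.
* Quantile tail selection takes `ceiling(fraction × n)` copies with
  ties broken by `copy_id` order.
* bedGraph values are written with `%.17g`, so write → read reproduces
  runs exactly.
* All randomness flows through a private seeded RNG stream
  (`.Random.seed` is saved and restored), with per-replicate seeds
  derived from the base seed, so fixtures and shuffles are reproducible
  byte-for-byte and shuffle replicates are independent of execution
  order.

## Problem sizes used by the test-suite

The suite verifies the interval and signal operations against per-base
brute-force oracles on 500 random instances (genomes ≤ 3 kb), the
tandem sweep against an all-pairs oracle on 1000 random annotations
including exact-500-bp boundaries, the shuffled null against a
Monte-Carlo placement oracle (200 shuffles × 500 peaks on a 2 × 500 kb
fixture), planted-gradient recovery over 100 seeded fixtures
(50 copies per clade, a 0.5-SD-per-rank effect), and the count-test
calibration on 5000 null copies.  These sizes keep the whole suite in
the ten-minute range while leaving the statistical checks
well-powered.

## A worked run

```{r example, eval = FALSE}
fx <- make_fixture(fixture_spec(seed = 1))
tracks <- simulate_tracks(fx)
tab <- abundance_table(tracks, fx$catalog)
age_trend(tab, fx$catalog, "H1X")      # positive rho: young-enriched
peaks <- simulate_peaks(fx)
enrichment_report(peaks$H1X, fx$catalog, fx$genome, fx$blacklist,
                  n_shuffles = 30, seed = 1)
```

The same stages are scriptable from YAML configs through
`run_stage()`, which writes TSV outputs plus a JSON manifest (input
checksums, parameters, seed, package version) for every run.

## Limitations

The peak caller, read aligner, and Hi-C compartment caller are out of
scope — peaks, alignments and compartment segments are consumed as
inputs.  The expression test is a calibrated stand-in, not a shrinkage
GLM; effect ranking near the significance boundary will differ from
DESeq2-style moderation, and the classification layer accepts external
results for that reason.  Multi-mapping ambiguity is modeled only
through the `n_hits` field (no EM reassignment).
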