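---
title: "devomap: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{devomap: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

devomap compares skeletal-muscle-style developmental time courses between
two conditions (breeds, strains, species) and scans two populations for
selective sweeps. This vignette is the package's own account of the
statistics it implements, the assumptions behind them, and the design
choices made where the method left room.

## Stage alignment by mapping scores and a maximum trace

The core question is whether two dense developmental time courses run in
register, and if not, which condition reaches each transcriptional state
first. The method works in three steps.

**Development-associated genes (DAGs).** For each time point *t* of a
condition, a gene is a DAG when its abundance exceeds `rpkm_min = 1.0`
(expressed above background) *and* its within-gene Z score at *t* exceeds
`z_min = 1.5`. Z scores are computed per gene across the condition's time
points on the raw abundance scale (`(x - mean)/sd`, sample sd). Both
inequalities are strict. A DAG set is therefore the signature of a stage:
the genes peaking there relative to the rest of development.

**Mapping scores.** For a time-point pair (*i*, *j*) of conditions A and
B, the overlap *k* of DAG(A, i) and DAG(B, j) is scored with the
upper-tail hypergeometric probability P(X >= k), drawing |DAG(A, i)|
genes from a universe of N genes of which |DAG(B, j)| are "successes".
The universe is the set of genes present in both conditions' matrices —
one fixed N keeps scores comparable across cells. Raw P-values are
Bonferroni-corrected with m = T_A x T_B (all tested pairs), and the
mapping score is -log10(corrected P), floored at 0. Corrected P is
clamped below at 1e-300, capping scores at 300 and keeping every cell
finite. The test is one-sided by construction: only enrichment of shared
DAGs, not depletion, indicates stage correspondence.

**Maximum trace.** Scores form a T_A x T_B matrix M. The alignment is the
monotone staircase path from M(1,1) to M(T_A, T_B) — moves right, down or
diagonal — that maximizes the summed score over the cells it passes
through, endpoints included. The dynamic program accumulates, for each
cell, the best attainable sum from (1,1); traceback starts at
(T_A, T_B). Ties during traceback are resolved deterministically:
diagonal first (biasing toward synchrony), then vertical, then
horizontal. The staircase move set is the minimal one consistent with a
path that must visit both corners and may map one stage of A to several
stages of B or vice versa; continuous-time warping with interpolation is
deliberately out of scope.

**Lag summary.** For each A time point, the B span is the set of column
indices sharing trace cells with it, and the lag is
median(B index) - A index. Positive lag means the row condition maps to
*later* column time points — the row condition is developmentally ahead
and the column condition lags. The modal lag over interior time points
(the two endpoints are forced to the corners) summarizes the global
offset; modal ties break toward zero for a conservative call.

## Differential-expression layers

The sampling design the package emulates pools RNA per time point, so
there are no biological replicates per library; phase or time-point
columns serve as replicates instead. All tests therefore run on
log2(x + 1)-transformed abundances with ordinary linear-model machinery
rather than count-based models, and counts never enter the pipeline.

* **Two-group test**: Welch's unequal-variance t-test; fold change is the
  difference of group means on the log2(x + 1) scale; significance at
  |log2 FC| >= 1 and BH FDR <= 0.05. Genes below a 0.1 abundance floor
  in both groups are excluded before testing (and counted). Groups with
  zero variance receive a variance floor equal to the 5th percentile of
  the positive per-gene pooled variances, so perfectly separated genes
  get large finite statistics instead of infinities; genes identical in
  both groups are null by construction (FC 0, P 1).
* **Phase-specific genes**: one phase versus the other three, both
  conditions pooled, keeping genes *higher* in the phase at FDR <= 0.05
  and fold change >= 2 (log2 FC >= 1). A gene passing for two phases is
  assigned to the one with the larger fold change, making per-phase
  lists disjoint.
* **Trajectory differences**: per gene, the interaction F-test between
  the nested models `log2(x+1) ~ condition + t` and
  `log2(x+1) ~ condition * t`, with t the ordinal time index 1..T
  (prenatal and postnatal day scales are incommensurate, so calendar
  days are not used). BH control at FDR <= 0.05. The 1-df interaction
  test asks whether the two conditions' *linear trends* differ; under a
  strongly curved shared trajectory the residual absorbs the lack of
  fit and the test turns conservative. Type-I calibration is therefore
  checked on flat-trajectory null simulations, where the model is
  correctly specified; observed rejection at nominal 0.05 lands within
  ±0.02 on 2,000 genes.

## Co-expression modules

Genes with coefficient of variation above 0.5 (sample sd over mean,
strict) are clustered on Z scores of both conditions' concatenated time
points using `stats::kmeans` with 10 random restarts under a fixed seed,
keeping the restart with the smallest within-cluster SSE. The number of
clusters is guided by the figure of merit: leave one column out, cluster
on the rest, and measure the root-mean-square deviation of the left-out
column from its cluster means, summed over left-out columns and
multiplied by the adjustment sqrt(n/(n - k)); the suggested k is the
elbow (maximum second difference) of the curve, and k remains
user-overridable. The k-means++ initializer was considered and not used:
base R's Hartigan–Wong with multiple restarts is the standard tool here,
and every recovery property (exact ARI = 1 on separated archetypes,
best-of-restarts SSE) holds identically under it.

## ceRNA triplet networks

Candidate miRNA-target pairs come either from externally computed
prediction lists (the intended production input) or from the built-in
canonical seed matcher (7mer-m8: reverse complement of miRNA positions
2-8; 7mer-A1: reverse complement of positions 2-7 followed by an A
opposite position 1; 8mer: both), case-insensitive with U = T, counting
non-overlapping sites. Hybridization energies are not modeled. Pairs
survive when expression across both conditions' concatenated time courses
shows R < -0.5 with P < 0.05 (Pearson; two-sided P from the
t-distribution on n - 2 df). Triplets join one miRNA's surviving lincRNA
and mRNA partners and are kept when the lincRNA-mRNA correlation passes
the positive arm (R > 0.5, P < 0.05) — so every emitted triplet satisfies
all three sign constraints by construction. Triplets split into two
opposing-trend networks by Spearman correlation against the time index:
both lincRNA and mRNA trending down (rho <= -0.3) is network I (miRNA up),
both up (rho >= 0.3) network II; the threshold 0.3 is a package default
since only the observed pattern, not a partition rule, is prescribed.
Guilt-by-association annotation (co-expressed protein-coding partners at
R > 0.5, P < 0.001) is reported as a list; enrichment against external
databases is out of scope.

## Population-genomic scan

* **Filtering**: biallelic SNPs only; call rate >= 90%; overall minor
  allele frequency >= 5% (boundaries inclusive; exclusion counts logged).
* **Diversity**: per-site pi is the average pairwise difference among
  called alleles, `2 c_ref c_alt / (n (n-1))`; window theta-pi divides
  the per-site sum by the full window span (per-bp), windows of 50 kb
  advancing 10 kb, anchored at position 1; trailing partial windows are
  kept and flagged.
* **Differentiation**: Weir & Cockerham (1984) per-site variance
  components with missing-aware sample sizes; the window estimate is the
  weighted ratio sum(a)/sum(a+b+c). Negative estimates are retained
  unclamped. Windows with fewer than 10 usable SNPs are excluded.
* **Sweep calls**: the log2 ratio of the two populations' window
  diversities is computed on windows where both are positive; windows
  with zero diversity in either population are excluded rather than
  pseudocounted, because a pseudocount distorts exactly the tails the
  scan reads. Thresholds are empirical quantiles of the analyzed
  windows — top 5% FST jointly with the 5% ratio tails (low ratio: sweep
  in the numerator population A; high ratio: sweep in B). Any published
  per-dataset cutoff values are properties of that dataset's empirical
  distribution and are never hard-coded. Quantiles are computed after
  the SNP-count exclusion. In the degenerate case where the two ratio
  tails collapse onto one value (e.g. all windows identical), a window
  hitting both tails has no direction and receives no call. Candidate
  windows of the same population that overlap or are book-ended merge
  into regions; genes overlapping a region by >= 1 bp (BED input treated
  0-based half-open, GFF3 1-based inclusive) are the selected genes.
* **Structure**: LD decay uses composite (genotype) r² — squared Pearson
  correlation of dosage vectors, pairwise-complete — for all pairs
  within 300 kb, averaged in 100-bp distance bins; phasing is out of
  scope and composite r² tracks haplotype r² closely at these sample
  sizes. PCA standardizes dosages by sqrt(2p(1-p)) per SNP
  (drift-variance scaling) with mean imputation of missing calls.
  The NJ tree uses 1 - IBS distances; negative branch lengths are
  clamped to zero with the excess moved to the sister edge; bootstrap
  support resamples SNP columns (200 replicates by default, seeded).

## What the synthetic generators emulate — and what they do not

**Expression.** Trajectory archetypes cover the module shapes the
analyses assume: abundance-affine monotone ramps (up/down), flat genes,
and phase-specific genes. The bump archetype has two components on the
log2 scale — a phase-wide plateau of half the amplitude and a narrow
Gaussian peak (sd 0.7 time-point indices) of the other half at a random
time point inside the phase. The split is deliberate: the plateau makes
the gene detectable as *phase*-specific by one-vs-rest testing, while
after the exponential back-transform the peak dominates the trajectory's
variance so the gene's Z score crosses the DAG threshold only at its
centre — the single-time-point resolution stage alignment requires. The
default amplitude is 6 log2 units over a baseline of U(-1, 2), spanning
roughly 0.5-250 RPKM, a realistic dynamic range for developmental
markers. Developmental lag is an index shift with boundary clamping
applied to condition B's mean trajectory for a random gene subset — an
ordinal, exactly invertible operation matched to the ordinal nature of
the alignment (no interpolation between stages). Noise is multiplicative
log2-Gaussian (default sd 0.2). The miRNA layer makes each true miRNA a
negative affine transform of its targets' mean trajectory with all
targets of one miRNA sharing direction and lag status, so the noise-free
limit attains Pearson R = -1 exactly; decoy miRNAs get independent noise
trajectories. Not emulated: count-level sampling noise and
overdispersion, biological replicates, batch structure, transcript-level
effects, and miRNA repression kinetics — so passing recovery tests shows
the inference machinery is correct, not that real data will be as clean.

**Genotypes.** The Balding-Nichols model draws per-population allele
frequencies Beta(p(1-F)/F, (1-p)(1-F)/F) around a U(0.1, 0.9) ancestral
frequency; it produces calibrated FST and diversity contrasts at desk
scale without coalescent machinery. Sweeps are frequency pushes (to
within 0.02 of fixation of the nearer allele), reproducing the
summary-statistic signature — depressed pi, elevated FST — rather than
hitchhiking dynamics; linkage, recombination maps and mutation-rate
variation are not modeled, so LD-based sweep statistics cannot be
validated against it. All randomness in both generators flows from one
explicit seed through deterministic per-operation substreams.

## Numerical choices and degenerate inputs

* Sample sd (n - 1) throughout; CV of a zero-mean gene is defined as 0
  and flagged instead of propagating NaN; constant genes get Z = 0.
* Mapping scores: corrected P clamped to [1e-300, 1], scores to [0, 300].
* Variance floor for zero-variance groups: 5th percentile of positive
  pooled variances (fallback 1e-8 if none).
* Classical MDS embeds on log2(x + 1) distances via Torgerson double
  centering; rank-deficient configurations (duplicate samples) are
  padded with zero coordinates; requesting more dimensions than samples
  minus one is an error; axis orientation is unidentifiable and tests
  treat sign flips as equivalent.
* k-means and FOM seed every restart explicitly; module ids are
  relabelled by decreasing size for stable output.
* Pearson P-values use the t approximation, undefined correlations
  (constant rows) are dropped from pair filters, and Spearman trend 0 is
  assigned to flat transcripts.
* Strictly increasing positions per chromosome are enforced at load
  time; sites with fewer than 2 called alleles in a population are
  skipped for pi, and FST sites need at least one called diploid per
  population.

## Problem sizes used by the test and acceptance runs

Simulation-backed checks run at 27 time points x 2,000 genes for
alignment and calibration, 1,000 genes for phase recovery, 20,000 SNPs /
20 diploids per population / 20 Mb with one 1-Mb sweep for the genomic
scan, 150 genes x 12 columns for module recovery, and up to 6x6 matrices
for exhaustive path enumeration — sizes at which every ground-truth
recovery is sharp while a full run stays in the seconds-to-minutes
range.

## Known limitations

Alignment resolution is bounded by time-point spacing; lags are ordinal,
not in days. The hypergeometric universe and Bonferroni factor are
conventions (exposed as arguments) since the method definition leaves
them open. Welch-on-log2 differential calls are not count-aware and
inherit the pooled design's lack of replicates. The sweep scan's
empirical-quantile thresholds always call ~5% of windows candidates on
null data by construction; it reports outliers of this dataset, not
absolute evidence of selection. Composite LD r² slightly understates
haplotype r² at low frequencies. The guilt-by-association list transfers
annotation only by correlation and is not an enrichment test.
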