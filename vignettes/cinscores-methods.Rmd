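---
title: "Scoring chromosomal instability from segmented copy-number profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring chromosomal instability from segmented copy-number profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cinscores)
```

## The problem

Tumour genomes destabilise in two distinguishable ways. Whole-chromosome
(numerical) instability produces gains and losses of entire chromosomes —
aneuploidy accumulating through chromosome mis-segregation, often on the
heels of a whole-genome doubling (WGD). Structural instability produces
sub-chromosomal gains, losses and rearrangement-associated copy-number
steps, and travels with homologous-recombination deficiency rather than
with WGD. Treating "CIN" as one number blurs this distinction; this
package computes separate per-sample surrogates for each axis from a
standard input: a segmented **absolute** copy-number profile plus an
externally estimated sample ploidy (ABSOLUTE-style — ploidy is consumed,
never estimated here).

## The scores

Let the segment copy numbers and the sample ploidy be rounded to the
nearest integer, and let all sums run over the 22 human autosomes (sex
chromosomes are dropped on read).

**NCS.** For each autosome, compute the fraction of *covered* segment
length whose integer copy number differs from the integer ploidy. The
chromosome counts as a whole-chromosome change when this fraction is at
least 0.75; the NCS is the number of such autosomes (0–22). Measuring
deviation against the sample's own integer ploidy makes the score
WGD-invariant by construction: doubling every copy number together with
the ploidy changes nothing.

**SCS.** Per autosome, compute the length-weighted modal integer copy
number; every rounded-and-merged segment of length ≥ 1 Mb whose copy
number differs from the mode counts one structural change; the SCS is the
total. Ploidy is not used (except as a modal tie-break, below).

**WGII.** The unweighted mean over covered autosomes of the
changed-fraction used by the NCS; stored as a fraction in [0, 1] (the
percentage form is a display concern). WGII and NCS are near-collinear on
cohorts dominated by whole-chromosome events, which the package's own
acceptance script quantifies (Pearson r ≈ 0.998 on the default synthetic
cohort).

### Numerical choices

These rules are deliberately pinned down so results are bit-reproducible:

- *Rounding ties*: x.5 rounds half away from zero ("nearest integer"
  alone is ambiguous at ties).
- *Covered vs assembly length*: all fractions are of **covered** segment
  length. Array platforms do not cover acrocentric arms; against assembly
  length a whole-chromosome call could be unreachable on such chromosomes.
  Chromosomes with zero coverage are excluded from the WGII denominator
  and never counted by the NCS.
- *Merging*: adjacent (touching) segments with equal integer copy number
  are merged before counting, so the SCS is independent of segmentation
  granularity; a coverage gap blocks the merge.
- *Modal ties*: when two copy-number states tie for the length-weighted
  mode, the tie breaks toward the integer ploidy when ploidy is available,
  else toward the smaller copy number — the backbone should not be counted
  as aberrant.
- *Coordinates*: internal convention is 0-based half-open; the TCGA SEG
  dialect (1-based inclusive) is the default input dialect and conversion
  happens only at the boundary. An optional log2-ratio input converts via
  CN = ploidy · 2^log2ratio when explicitly requested.
- *NCS and SCS are counted independently*: a chromosome counted as a
  whole-chromosome change can still contribute structural counts if its
  interior deviates from its own mode; the two definitions are applied
  as written, without cross-exclusion.
- Segments with missing copy number are dropped with a logged count, not
  imputed; how segments spanning centromeres or assembly gaps were
  originally handled is unknowable from a SEG file, so all covered bases
  are treated equally.

## What the synthetic generator emulates

`simulate_cohort()` produces multi-cohort datasets with the statistical
structure the downstream analysis assumes, plus the ground truth needed
for recovery tests:

- **Karyotypes.** Baseline copy number 2, or 4 for WGD samples (drawn per
  cohort with probabilities 0.2/0.35/0.5 recycled across cohorts). Whole-
  chromosome changes are Poisson with mean 1.5 (8 given WGD), each setting
  a chromosome to ploidy ± 1 — this WGD mixture yields the characteristic
  bimodal NCS with WGD samples in the upper mode. Structural events are
  negative-binomial (mean 4, size 1.5 — right-skewed, as structural burden
  is), with log-uniform lengths from 100 kb to 20 Mb (sub-1 Mb events are
  real but must not count toward the SCS) at modal ± {1, 2}.
- **Exact recoverability.** Structural events are placed only on
  chromosomes not selected for whole-chromosome change, with a gap between
  events and a per-chromosome coverage budget of 40 % so the backbone
  stays modal; hence the planted whole-chromosome count *is* the NCS truth
  and the count of placed ≥ 1 Mb events *is* the SCS truth. On near-fully
  aneuploid genomes (few eligible chromosomes left) events that cannot be
  placed within bounded retries are dropped and never enter the truth.
  Copy-number noise is Gaussian (sd 0.2) truncated at ± 0.45, and ploidy
  jitter uniform within ± 0.25: both strictly inside the 0.5 rounding
  margin, so integer rounding recovers the planted karyotype with
  probability one — an unbounded noise tail would otherwise corrupt a
  predictable ~1 % of segments and make exact-recovery tests impossible.
- **Lattice.** All breakpoints sit on a 10-kb lattice, emulating
  array-probe segment resolution. This also lets the test suite's
  independent oracle expand profiles to per-unit copy-number vectors and
  tally them directly: with lattice-aligned boundaries the per-unit tally
  equals a per-base tally exactly, including the floating-point value of
  every changed fraction.
- **Clinical layer.** Survival is exponential with hazard
  h0 · exp(β · 1[score > median]) (defaults h0 = 1/1500 days⁻¹,
  β = log 2) under independent uniform censoring on [0, 3650] days —
  the standard two-group proportional-hazards testbed. Responder labels
  are Bernoulli with log-odds linear in the standardised score; the
  default slope is negative (radiotherapy responders tend to carry lower
  whole-chromosome burden). HRD tracks the structural event count and the
  aneuploidy score the whole-chromosome count, each plus Gaussian noise;
  the remaining indices are pure noise, and a hypermutated-MIN flag is
  Bernoulli(0.1).
- **Features, alterations, drugs.** Planted expression/pathway features
  equal ρ·z + √(1−ρ²)·ε (ρ = 0.5) inside their planted cohorts —
  recurrent features in 10 cohorts (enough to clear the ≥ 7-cohort
  recurrence rule), sporadic ones in 3 (too few). The alteration matrix is
  Bernoulli per gene; planted genes act *before* profile realisation by
  adding Poisson(Δ) whole-chromosome and structural events to carriers
  (Δncs = 4, Δscs = 11 for the TP53-like driver; the extra structural
  events are drawn ≥ 1 Mb so the mean SCS shift equals Δ exactly, rather
  than being attenuated by the length filter). A gene at carrier frequency
  1.5 % exercises the minimum-group-size exclusion. The drug screen sets
  AUC = baseline − slope·z + noise with one potent planted compound (low
  baseline ⇒ median sensitivity > 0.5 after global normalisation), one
  weak one (high baseline ⇒ ≤ 0.5) and zero-slope nulls.

What the generator does **not** emulate: clonal/phylogenetic structure,
allele-specific copy number, purity contamination, focal
amplicon/chromothripsis length distributions, platform-specific noise or
segmentation artefacts, and correlated censoring. Passing tests therefore
demonstrate that the algorithms implement their definitions and that the
statistical stages have the advertised operating characteristics under a
clean generative model — not that any biological conclusion transfers to
real cohorts.

## The statistical stages

- **Correlation screens** use Spearman's rank correlation
  (pairwise-complete, asymptotic t p-values), with Benjamini–Hochberg FDR
  within each cohort's screen. The recurrence filter requires rho ≥ 0.3
  with FDR < 0.05 in at least 7 cohorts, positive correlations only; both
  thresholds are arguments.
- **Alteration regression** is ordinary least squares of the score on an
  alteration indicator plus cohort fixed effects, with classical two-sided
  t tests and BH FDR across tested alterations. A moderated
  (empirical-Bayes) variance estimator would differ only in the
  small-sample pooling of residual variances across thousands of models;
  with a single continuous response per score the classical t test is the
  transparent choice, and the test suite cross-checks the point estimates
  against limma's fit on the same design. Eligibility demands ≥ 20
  samples in *both* the altered and wild-type groups; alterations aliased
  with cohort are flagged and excluded from the FDR family. With a single
  cohort the coefficient reduces exactly to the two-group mean difference.
- **Survival** stratifies at the within-cohort median (ties to the low
  group; flag-switchable), then applies the two-group log-rank test and a
  univariate Cox model for the high-group indicator. Cox fitting delegates
  to the survival package with **Breslow** tie handling, which keeps the
  hazard ratio exactly invariant under dataset duplication (Efron's
  approximation does not); five-year survival is read from the
  Kaplan–Meier curve at 1826 days. Groups without events are flagged
  unreliable rather than dropped silently.
- **Treatment response** is the two-sided Wilcoxon rank-sum test with
  normal approximation; fully tied inputs return p = 1 by convention.
- **Drug screen**: sensitivity = 1 − min–max-normalised AUC. The
  normalisation is *global* over the screen by default — one minimum, one
  range — so per-compound median sensitivities are comparable on a common
  [0, 1] scale; a per-compound mode exists because the choice is genuinely
  ambiguous. Since the index is a strictly decreasing affine map of AUC,
  the Spearman correlation against a score equals minus the raw-AUC
  correlation exactly. Candidates need FDR ≤ 0.05 *and* median
  sensitivity > 0.5; compounds with fewer than 3 usable cell lines are
  reported untested, not as nulls.
- **Hypermutated exclusion** accepts a boolean MIN flag or a
  user-supplied cutoff on a MIN score; no default cutoff is imposed
  because none is defensible a priori.

## Problem sizes and determinism

The test suite and `scripts/acceptance.R` use cohorts of 200–1000 samples,
1000-replicate null calibrations and 200-replicate recovery studies —
sizes at which binomial noise on an empirical 5 % rate is ± 0.7
percentage points and CI-coverage estimates resolve to ± 2 %. Replicate
studies of downstream statistics draw from the generator in truth-only
mode (`scores_only = TRUE`), which realises the same event model without
materialising segments; the separate exact-recovery property (computed
score ≡ planted truth on fully realised profiles) is what licenses that
shortcut. All randomness flows from a single integer seed; fixed-seed
pipeline reruns are byte-identical, which the acceptance script verifies
file by file.

## Known limitations

- Scores are as good as the input segmentation and ploidy call; no purity
  or ploidy re-estimation, re-segmentation or liftover is attempted.
- The 75 % / 1 Mb / 0.3 / 7-cohort / 20-sample / 0.5-median thresholds are
  field conventions, exposed as arguments but not re-derived.
- The OLS regression reports homoscedastic t tests; counts such as the
  NCS are mildly heteroscedastic across groups, which the calibration
  replicates show is immaterial at these sizes (type-I within
  [3.5 %, 6.5 %]).
- Arm-level aneuploidy scores, subtype-stratified survival and gene-set
  enrichment are out of scope.
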