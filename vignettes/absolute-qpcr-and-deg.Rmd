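---
title: "Methods: absolute-scale qPCR normalization and count-based differential expression"
author: "absquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: absolute-scale qPCR normalization and count-based differential expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(absquant)
```

## The measurement problem

Somatic embryogenesis (SE) induction experiments on conifer explants
compare gene expression across explant series — here, a responsive clonal
series, its nonresponsive same-genotype sibling, and nonresponsive
genotypes — over a multi-week induction time course. Two measurement
modes are involved. Absolute qPCR reports transcript quantities as
molecules per 10 ng of total RNA, which makes quantities comparable
across genes, samples and runs, but leaves the technical variance of
sample preparation (RNA extraction, quantification, reverse
transcription) in the data. Bulk RNA-seq of responsive vs nonresponsive
explants gives gene-level counts whose differential analysis needs a
count model, multiplicity control and an induction-direction filter.

`absquant` implements both stages plus the synthetic data needed to
verify them by parameter recovery.

## Sample-specific normalization

The procedure assumes that a small set of reference genes is biologically
stable across the time course, so that their sample-to-sample variation
is primarily multiplicative technical scaling. For each reference gene
the quantity in a sample is divided by the mean of that gene over all
samples of the same explant series, giving a fractional value; the
fractions are then averaged (arithmetically, by default) across reference
genes within each sample. The resulting factor is a per-sample estimate
of its relative technical scale; dividing every quantity in the sample by
it removes that scale **without leaving absolute units** — the central
advantage over relative quantification.

Properties that follow from the construction, and that the test suite
asserts:

- within each series, the factors average to exactly 1 (floating-point
  tolerance 1e-9);
- with a single reference gene, normalization maps every reference
  quantity onto its series mean exactly;
- on synthetic data with zero measurement error, the estimated factors
  equal the true technical scales centered by their series mean, to
  floating-point round-off;
- normalization strictly reduces the within-series coefficient of
  variation of reference quantities in essentially every replicate at
  realistic noise (25% measurement CV).

Design choices that were genuinely open:

- **Arithmetic vs geometric fraction averaging.** The arithmetic mean is
  the default because it alone guarantees a per-series factor mean of
  exactly 1; the geometric mean (natural for multiplicative error) is
  available via `normalizationFactors(..., method = "geometric")`.
- **Zero or missing reference quantities are errors**, never imputed: a
  zero reference would make the factor zero or undefined, and a missing
  one silently biases the series mean. The error names the sample and
  gene.
- **Series membership is taken from explicit labels** and never parsed
  out of sample names.
- The divergence diagnostic reports `min%`, `max%` and the half-range
  `(max − min)/2`, a conservative "roughly ±x%" reading of factor spread
  (e.g. extremes of 0.67 and 1.35 read as 67%–135%, about ±34%).

## Time-course profiles and association calls

Profiles are per-(gene, series) trajectories of normalized quantity over
induction days; replicates at the same (series, day) are averaged first.
Visual judgments like "the two profiles are nearly identical" are
formalized by the distance

\[ d(a, b) = \frac{1}{T}\sum_{t} \left| \log_2 \frac{q_a(t) + \varepsilon}{q_b(t) + \varepsilon} \right| \]

with pseudocount ε = 1 molecule / 10 ng by default, so that transcripts
that fall to zero at some days (as the early-transient contig in the
study system does by day 15) remain comparable. The distance is a
pseudometric; fold change is its natural scale because fold change is
the field's comparison currency.

`classifyAssociation()` encodes the inference that the four-series
design affords: a gene is **responsiveness-associated** if the
responsive series and its nonresponsive clonal sibling separate by more
than the threshold (same genotype, different response — genotype factors
cancel); otherwise **genotype-associated** if the responsive series
separates from the nonresponsive genotypes on average; otherwise
**none**. The default threshold of 1.0 log2 unit (2-fold) mirrors the
common convention that smaller differences are not biologically
meaningful; no published number constrains it, so it is a tunable
parameter, and calls are monotone in it (raising the threshold never
creates an associated call).

## The differential-expression stage

**RPKM.** `count / (gene length in kb × library size in millions)`, with
library size the column sum unless supplied. RPKM is used for reporting
(phenotype means, fold differences, summary averages); testing operates
on counts.

**Dispersion.** The tagwise (per-gene) NB dispersion is estimated by a
within-group method of moments, `(variance − mean)/mean²`, pooled across
the two phenotype groups with degrees-of-freedom weights, floored at 0,
then shrunk toward the all-gene median with weight `priorWeight`
(default 0.5 — an even compromise between a per-gene estimate that is
very noisy at 3 replicates and a stable common value). This is the
package's own documented estimator; matching any specific tool's
"default tagwise dispersion" is explicitly not a goal, and the estimator
is validated against its simulation behavior instead (Poisson data give
dispersions near 0; NB data at dispersion 0.1 with 6 samples per group
give a median estimate within [0.05, 0.2]).

**Exact test.** Under equal means, per-sample NB counts at dispersion φ
give group totals that are NB with sizes n/φ, and the conditional
distribution of one group's total given the grand total does not depend
on the mean — it is negative hypergeometric, reducing to binomial in the
Poisson limit φ = 0. The two-sided p-value sums all split probabilities
at most as large as the observed one (ties included, a standard exact
test convention), so p ∈ (0, 1] and equal group sums give p = 1. Because
conditioning requires comparable libraries, each day's samples are first
scaled to their geometric-mean library size and rounded to integer
pseudo-counts. The implementation is verified three ways: exhaustive
agreement with a brute-force convolution of per-sample pmfs for every
total ≤ 30 at dispersions {0, 0.1, 1}; agreement with an independent
reference implementation (edgeR's small-p exact test) on random data;
and a simulated-null rejection rate at 0.05 inside the 99% binomial
interval.

**FDR and filtering.** p-values are BH-adjusted per day. The filter
keeps genes with adjusted p < 0.05 and a phenotype-mean RPKM ratio
showing ≥ 2-fold induction in one phenotype (ratio ≥ 2 → responsive
induced, ≤ 0.5 → nonresponsive induced). Both thresholds are arguments;
a flag switches to raw-p filtering. Filtering on the adjusted value is
the default because FDR correction is stated as applied in this
analysis tradition; an infinite ratio (nonzero over zero mean) counts as
responsive-induced, an undefined 0/0 ratio is dropped. Summary tables
count DEG per (day, induced phenotype) and average the induced
phenotype's mean RPKM over them — the induced phenotype only, since that
is the expression level the induction claim is about; empty cells report
a count of 0 and an undefined average.

## What the generators emulate — and what they do not

`simulateQpcrData()` draws one sample per series × day (defaults: 4
series × days {0, 3, 7, 15, 21} — the five-point induction grid; the
day values are configurable since only their count is fixed by the
design). Observed quantity = true profile × technical scale ×
measurement noise, where

- the technical scale is log-normal with mean-0 log (`techScaleSigma`
  default 0.16, chosen so twenty sampled factors typically span about
  0.67–1.35, the divergence actually observed in this kind of
  experiment);
- measurement noise is multiplicative log-normal with unit mean at
  `measurementCV` default 0.25, the reported accuracy of the absolute
  quantification methodology;
- reference genes are flat at fixed baselines (10000 and 7000 molecules
  / 10 ng for the default two);
- targets follow three shapes: flat; late-induced (geometric ramp to
  `peakFold` at the final day, dehydrin-like — default baseline 200,
  peak fold 10); early-transient (peak at the first positive day,
  halving at the next, zero from day 15 — default baseline 36, peak fold
  10, i.e. a peak near 360 molecules / 10 ng, the scale observed for the
  early MADS-box-like transcript).

`simulateCountData()` draws gene lengths uniform in 300–3000 bp,
relative expression log-normal (sdlog 1.2, normalized to sum to 1),
library sizes uniform in 0.8–1.2 million reads, and NB counts with mean
`library size × relative expression × fold` at dispersion 0.1 over the
2 × 4 × 3 = 24-sample design. A fraction `deFraction` of genes carries a
true fold (uniform in `foldRange`, default 2–8) in the responsive
phenotype at every day; non-DE genes have exactly equal means in the two
phenotypes. `dispersion = 0` substitutes Poisson sampling and flags it
in the truth object.

Deliberate simplifications, hence what passing tests do *not* show about
real data: biological replicates are independent NB draws (no
replicate correlation structure, no batch effects); DE folds are
constant across days rather than time-varying; there is no
compositional / normalization bias between libraries beyond the planted
excess, so the column-sum library size is adequate where real data
might need trimmed-mean normalization; qPCR noise is purely
multiplicative log-normal with no day-dependent variance, whereas the
real series showed larger variance at early time points.

## Numerical choices and degenerate inputs

- Exact-test probabilities are computed in log space and normalized by
  their sum (not a closed-form denominator); the rejection region uses a
  relative tie tolerance of 1e-10. A grand total of 0 returns p = 1.
- Library scaling rounds to the nearest integer pseudo-count; rounding
  is the price of keeping the conditioning exact.
- Read trimming applies head-trim → length cap → minimum-length drop in
  that fixed order (the conventional cleaning order; with the default
  policy: remove the first 15 bases, cap at 205 — or 170 for the second
  sequencing batch — then drop reads under 20 bases). Reads shorter than
  the head trim vanish and are dropped; quality strings are trimmed
  identically.
- The contig filter reads "minimum contig size 500" inclusively
  (length ≥ 500 kept) and preserves input order.
- The gDNA check is strict: fewer than 5 genomes per 10 ng RNA passes,
  exactly 5 fails.
- All generators save and restore the caller's RNG state; identical
  seeds give byte-identical outputs.

## Problem sizes

The test suite and the acceptance script size their simulations to be
statistically informative at desk scale: 2000 genes for null-calibration
and dispersion-recovery checks, 100 seeded replicates of the 20-sample
qPCR design for the CV-reduction rate, exhaustive exact-test enumeration
up to grand total 30, and a 2000-gene / 10-planted-gene recovery run for
DEG sensitivity. These sizes were chosen so binomial confidence
intervals on the measured rates are tight enough to detect real defects.

## Known limitations

- The exact test assumes a common dispersion for the two groups of a
  gene and integer pseudo-counts; very unequal library sizes make the
  rounding step lossier.
- The moment-based dispersion estimator is biased downward for strongly
  expressed genes at very small replicate numbers; the shrinkage weight
  trades that against stability, and no claim of equivalence to any GLM
  or empirical-Bayes estimator is made.
- Association calls depend on the pseudocount for transcripts near zero;
  ε = 1 molecule/10 ng is negligible for expressed genes but caps the
  fold attributed to on/off transitions.
- `runPipeline()` covers the normalize → profile and count → test →
  filter → summarize paths; read mapping, assembly and annotation are
  upstream tools' territory and out of scope.
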