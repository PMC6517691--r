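---
title: "Methods: age, sex and gut microbiota diversity in microage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: age, sex and gut microbiota diversity in microage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of the statistical procedures it
implements, the choices behind them, and what its synthetic-data tests do
and do not establish.

## The analysis

The package analyses a cross-sectional adult cohort given two tables: an
SV (sequence variant) count table, samples by SVs, and per-sample metadata
with age in years, sex, and optional antibiotic-use and cardiometabolic
columns. Adults are ages 20–69 inclusive; samples outside that range are
excluded up front, and the range is split at 45 years into young adults
(20–45) and middle-aged adults (46–69). All exclusions are logged with
reasons, and included plus excluded samples always account for every input
sample.

**Rarefaction and alpha diversity.** Counts are rarefied to a common depth
(default 1250 reads) by per-sample sampling without replacement — a
multivariate hypergeometric draw — with samples below the depth dropped,
never padded. Draws come from one seeded generator applied in sample-id
sort order, so results are independent of input row order; repeating the
rarefaction at the same depth is the identity. Richness is the count of
observed SVs. The Shannon index is reported in bits (base-2 logarithm,
computed via `vegan::diversity(base = 2)`), the convention of the QIIME 2
ecosystem; published adult-cohort tables in which mean Shannon exceeds the
natural log of mean richness are only arithmetically possible in base 2,
which is why base 2 is the default, with the base exposed as an argument.

**Age-trend models.** Each metric is regressed on age twice: a simple line
and a linear spline on the basis $\{1, a, (a-45)_+\}$. The change-of-slope
parameterisation is equivalent in fit and AIC to a two-segment-slope basis;
the reported segment slopes are $b_1$ and $b_1 + b_2$, the latter with its
delta-method standard error from the coefficient covariance. AIC uses the
full Gaussian log-likelihood, counting the error variance as a parameter
(what `stats::AIC` returns), so for the nested pair the identity
$\mathrm{AIC}_{simple} - \mathrm{AIC}_{spline} = n\log(RSS_{simple}/RSS_{spline}) - 2$
holds exactly and is asserted in the tests to 1e-8. Model selection takes
the strictly lower AIC, with exact ties resolved to the simple model on
parsimony. Stratified models fit `metric ~ age + sex` within each age
group; the male-indicator coefficient is the adjusted men − women
difference. The pooled-with-sex-term form is the primary estimate of that
difference (sex-stratified fits are also available via subsetting) because
a single adjusted contrast is what a "difference after accounting for age"
is; this is a documented choice where either reading is defensible.
Loess curves (span 0.75, degree 2, tricube weights — the common plotting
defaults, exposed as arguments) are fitted per sex for visualisation only.

**Multiple testing.** P values are adjusted with Benjamini–Hochberg step-up
within one analysis batch: one cohort, one metric, and the set of reported
stratified terms (young/middle age slopes, sex differences, and
age-by-sex interaction tests). The batch label is recorded in the output so
the family behind every adjusted value is explicit. Any batching convention
is defensible; this one adjusts exactly the numbers a reader would scan
together. Wilcoxon p values from the microbiota-age comparisons are
adjusted jointly across the strata and training directions of one run.

**Cardiometabolic risk scale.** The score is the sum of within-cohort
z-scores of natural-log-transformed waist circumference (cm),
triglycerides (mg/dL), insulin (µU/mL), diastolic blood pressure (mmHg)
and hsCRP (mg/L). The log base is cosmetic (z-scoring absorbs it); the
z-scores are computed over the whole cohort by default, with a per-sex
option, since the pooling level is a genuinely open choice. A covariate
that is constant in the cohort has no dispersion to standardise and
contributes zero for every subject rather than failing — degenerate
synthetic scenarios stay runnable. Samples with missing or non-positive
covariates are excluded with logged reasons. Risk adjustment residualises
each metric on the score (the form in which adjusted diversity is usually
plotted); adding the score as a model covariate instead is supported
through the stratified fit's `covariates` argument.

**Microbiota age.** The feature set is the SVs present in at least one
sample of each sex; their counts are renormalised to relative abundances
summing to one. A random forest regresses age on these abundances with
`mtry = floor(p/3)`; the default 1000 trees keeps a desk run to seconds —
prediction variance at 1000 trees is small relative to the comparison
noise, as the replicate-based tests demonstrate, and the count is
configurable upward. Training-sex samples are scored by out-of-bag
prediction, test-sex samples by the full forest: using resubstitution
predictions for the training sex would centre its relative ages on an
optimistically tight calibration, and out-of-bag is the standard guard. The
calibration curve is a cubic smoothing spline (smoothness by generalised
cross-validation) of out-of-bag predictions on chronological age,
interpolated only within the training age range; outside it the boundary
value is used and the sample flagged as extrapolated. Relative microbiota
age is prediction minus calibration value at the sample's age. Group
differences are summarised as the women − men difference of medians (means
are also emitted; the estimator is a documented choice), tested two-sided
by Wilcoxon rank-sum — exact when both groups have at most 25 observations
and no ties, tie-corrected normal approximation otherwise. Age-group
analyses re-select shared SVs and retrain within each group.
Cross-validation profiles rank SVs by permutation importance (mean increase
in MSE; impurity importance by flag), then report mean ± SD of 10-fold CV
mean squared error for each top-k subset, with folds stratified by age
decile and fixed by seed so small-cohort estimates are stable.

## The synthetic cohort generator

No generative model for these cohorts exists in the literature, so the
generator is an artifact design: its job is to produce data whose
*statistical structure* matches what the analysis assumes, with every
planted effect recoverable and every null clean.

Per subject, an integer age is uniform on 20–69, sex and antibiotic flags
are Bernoulli, and a latent target richness follows the piecewise-linear
model `beta0 + beta1*min(age-20, 25) + beta2*max(age-45, 0)` plus a sex
offset, an antibiotic effect and Normal noise, clamped to at least 1 and at
most the pool size. Defaults (`beta0 = 95`, `beta1 = 0.9` SV/year,
`beta2 = 0`, sex offset −10 SVs, noise SD 8 SVs, antibiotic effect −12 SVs
in 15% of subjects, 3-year female shift, 1250-read rarefaction of
3000-read libraries) give cohort summaries — mean richness near 105–120,
young-adult slopes near one SV per year — of the same order as published
adult-cohort descriptive tables.

Composition comes from a global pool of 800 SVs with log-normal base
abundances (sdlog 0.3). The 200 highest-abundance pool members are
age-informative: each multiplies its abundance by
`exp(±1.5 * (logistic((age_eff - t)/4) - 1/2))`, a monotone ramp centred at
an SV-specific threshold spread over the age range, with directions
alternating so half rise and half fall with age. `age_eff` is chronological
age plus the female shift, so composition — not richness — carries the sex
difference in microbiota age. Each subject's SV subset is drawn by a
Gumbel top-k race on half the log-weights (exactly `R_i` SVs, so richness
is controlled by subset selection rather than zero-inflation), and counts
are one multinomial draw of the library depth over the subset.

Three generator details matter and were set once, by design reasoning
rather than by tuning to any test outcome:

* **Centred, direction-alternating ramps.** An uncentred, one-directional
  ramp makes within-sample abundance skew grow with age, so older samples
  lose more rare SVs at rarefaction and the realised richness trend is
  biased against the latent one. Centring and alternating keep the skew
  small and age-independent; simulation confirms the realised rarefied
  slopes track the latent 0.9/0.0 SV/year without systematic bias.
* **Ramp amplitude and width** (1.5 and 4 years) are the compromise between
  a compositional age signal a random forest can learn at realistic cohort
  sizes (out-of-bag variance explained in the 0.6–0.9 range, against the
  "low to moderate" values real cohorts show) and abundance skew small
  enough that a 1250-read sample observes nearly all of its ~100–120 SVs.
* **Informative SVs are the most abundant pool members**, so they are
  present in most subjects and the age signal is carried by abundance, not
  by presence alone.

What the generator does *not* emulate: real taxonomic covariance structure
(SVs are independent given age), overdispersion beyond multinomial
sampling, uneven community evenness (simulated Shannon values are higher,
~6.4 bits, than real stool communities at comparable richness), sequencing
error, chimeras, or longitudinal structure. Passing tests therefore show
the *procedures* are correct and the planted effects identifiable — they
do not validate the biological findings on real data, which require the
original cohort tables.

## Numerical and edge-case choices

* A constant response yields slopes of exactly zero and R² defined as 0
  (the floating-point ratio `summary.lm` produces there is meaningless).
* Rank-deficient strata (constant age), single-side-of-knot spline fits and
  sub-3-case fits raise errors naming the problem; single-sex strata drop
  the sex term with a warning rather than failing.
* Wilcoxon comparisons with a group under 3 return an undefined p with a
  warning rather than a misleading number.
* Every stage's randomness derives from one top-level seed fanned out to
  named per-stage seeds (recorded in the run log, all below 2³¹), so a
  pipeline re-run is byte-identical.
* Scenario and pipeline configs round-trip losslessly through YAML/JSON.

## Problem sizes in the test suite

The suite exercises cohorts of 120–1600 subjects. Replicated checks use 50
cohorts of n = 1000 for age-trend parameter recovery and AIC selection, 20
pipeline replicates of n = 1000 for the qualitative age/sex pattern, 10
replicates of n = 600 at 200 trees (both training directions) plus 20 null
replicates for the microbiota-age shift, one n = 600 cohort for the
CV-versus-number-of-SVs profile, and 20 replicates of n = 400 for
risk-adjustment neutrality. Oracle checks run brute-force
Benjamini–Hochberg on 1000 random vectors and full-enumeration Wilcoxon
tests on 500 random group pairs. These sizes give the replicate-level
properties comfortable margins while keeping a full run to a few minutes
on one CPU; they are package choices, not statements about the cohorts the
method is meant for.

## Known limitations

* The spline knot is fixed and user-specified, not estimated; cohorts whose
  diversity plateaus far from 45 years need the knot moved.
* Only two sexes are modelled, matching what the cohorts report; other
  values are excluded with a logged reason rather than guessed.
* The microbiota-age comparison assumes the two sexes share enough SVs for
  a common feature space; disjoint communities are an error, not a result.
* Relative microbiota age outside the training age range uses the boundary
  calibration value and is flagged; treat flagged samples with caution.
* The risk scale is a within-cohort construct; scores are not comparable
  across cohorts and carry no clinical calibration.
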