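---
title: "Quantifying proteotype variation through protein complexes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying proteotype variation through protein complexes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(proteovary)
```

## The problem

Individuals differ in their proteomes — their *proteotypes* — and much of
that variation is organized: subunits of a protein complex tend to rise and
fall together across individuals, because cells co-regulate the parts of a
machine. proteovary quantifies this organization from a proteins × samples
abundance matrix and known module catalogs (complexes, pathways,
compartments, chromosome groups, housekeeping/essential sets), and then asks
two biological questions: which complexes are *stable* (tight co-abundance)
versus *variable* across individuals, and how much of the variation in
complex abundance and in complex *stoichiometry* (the relative proportions
of subunits) is attributable to covariates such as genetic sex and diet.

The pipeline has five analytic stages, each exposed as ordinary functions
and orchestrated by `runPipeline()`:

1. **Preprocessing** — Shapiro–Wilk screening per sample, with log2
   transform and quantile normalization applied to datasets that fail it.
2. **Module recovery** — ROC/AUC of pairwise Pearson co-abundance against
   module co-membership, with a subsampled Mann–Whitney p-value.
3. **Complex landscape** — ranking complexes by median within-complex
   co-abundance, aggregating ranks across datasets, and testing consistency
   against permutation and decoy nulls.
4. **Stoichiometry** — trimmed-mean complex normalization, per-subunit
   variance z-scores, and stable/variable component calls within and across
   datasets.
5. **Covariate effects** — Cohen's d and t-tests on complex median
   abundance; empirical-Bayes moderated contrasts on complex-normalized
   data; cross-validated ridge-regression variance explained with
   permutation FDR.

A companion generator, `generateCohort()`, simulates multi-dataset cohorts
with planted modular covariance so that every stage has a recoverable
ground truth without downloading any external dataset.

## Preprocessing

Each sample's non-missing values are tested with the Shapiro–Wilk statistic
(`assessNormality()`, values subsampled to 5000 when larger, seeded).
`preprocessDataset()` applies log2 + quantile normalization only when more
than 10% of samples reject normality at p < 0.01: published matrices are
usually already normalized, and renormalizing them is harmless but
unnecessary. The 10% rule is this package's own operating point — the
decision is exposed through `force = "always"/"never"` for users who want
to pin it. Log base 2 is used throughout so that contrast coefficients read
directly as log2 fold-changes.

Quantile normalization follows the classic algorithm (k-th smallest value
replaced by the mean k-th smallest across samples, ties averaged) via
`limma::normalizeQuantiles(ties = TRUE)`; with missing values, reference
quantiles are interpolated on the common quantile grid, and missing entries
stay missing. Completeness filtering keeps proteins quantified in at least
half the samples (`>=`, so 10/20 survives).

## Module recovery by ROC/AUC

Condition positives are protein pairs sharing a module of a category;
negatives are an equal-sized random sample of quantified pairs sharing no
module of that category. For pathways, pairs that co-occur in a complex are
removed from the positives, so pathway-level co-variation is not simply
complex co-variation re-counted. Interaction positives use the combined
score > 0.7 (high-confidence) cutoff by default, with 0.5 and 0 available;
scores on the 0–1000 convention are rescaled to [0, 1] automatically.

The ROC sweep moves a threshold down the union of observed correlation
values; ties cross together, which prevents optimistic staircases. The
trapezoidal AUC is then exactly the Mann–Whitney concordance probability
with ties counted ½ — an identity the test suite verifies to 1e-9 against
exhaustive pair counting. Pairs need at least 6 jointly quantified samples
(`minOverlap`); Pearson correlations on fewer samples are too unstable to
rank. Because a handful of usable positives cannot support a ROC curve,
cells with fewer than 100 usable positives are reported missing (the
published analyses never ran below ~1500 positives).

The subsampled Mann–Whitney procedure (1000 draws of 1000 items by default)
reports the *mean* p over subsamples — a deliberately conservative effect
summary whose magnitude does not grow with the full list sizes. Lists
shorter than the subsample size are resampled with replacement, the open
behavior we had to fix: without replacement would silently shrink the test.

## The stable/variable complex landscape

For each complex with ≥ 5 quantified members, the median of all pairwise
subunit correlations summarizes its co-abundance; complexes are ranked per
dataset (average ranks on ties) and the rank *fraction* (rank divided by
the number of qualifying complexes) makes ranks comparable between datasets
with different catalogs. The aggregated landscape takes each complex's
median rank fraction over the datasets in which it qualifies; the top
quartile is classified stable, the bottom quartile variable. Quartile
thresholds are computed on the aggregated landscape rather than fixed at
published correlation anchors, because those anchors are properties of the
specific datasets they were derived from; `aggregateLandscape()` reports
the underlying `median_r` so users can read off their own cohort's
quartile correlation values.

Two nulls guard the landscape. *Decoy complexes* (`decoyComplexes()`) are
size-matched sets drawn from module-free proteins. *Within-protein
permutation* (`permuteWithinProtein()`) shuffles each protein's values
across samples independently — it preserves every marginal distribution
and missingness count while destroying all inter-protein covariance. The
permutation unit is a design choice (the procedure is described only as
"permuting the dataset" in the literature this implements); shuffling
within proteins is the strictest option that keeps per-protein abundance
distributions intact. `landscapeConsistency()` compares observed pairwise
Spearman correlations of complex ranks between datasets to the permuted
null with a two-sided t-test; with only two datasets there is a single
observed correlation, and the t-test degenerates to a one-sample test of
the null distribution against it.

## Stoichiometry decomposition

`complexNormalize()` subtracts, per sample, the symmetric trimmed mean of a
complex's quantified subunits (trim 0.25 from each side after sorting,
`floor(0.25 k)` values removed per side — the interquartile mean made
exact) from each subunit's log2 abundance. Subtraction in log space is a
ratio in linear space: what remains is each subunit's deviation from its
complex's overall abundance, i.e. stoichiometry. Samples with fewer than 3
quantified subunits give no reference; proteins in several complexes get
the average of their complex-specific normalized values in the combined
matrix, while per-complex values are retained for all downstream
per-(complex, subunit) statistics. Note that the reference absorbs a small
part of any real subunit shift (a 0.5 log2 planted shift on one of eight
subunits is recovered at roughly 0.43), an attenuation inherent to
self-referential normalization.

Per complex, the variance of each subunit's normalized values (subunits
quantified in ≥ 50% of samples, over samples with a defined reference) is
standardized to z-scores within the complex. Within one dataset, components
are called from one-sided standard-normal tails (variable above, stable
below, α = 0.05), with |z| > 1.5 kept as a separate display threshold for
figure-style output. The normal reference is an approximation: a z-score
standardized among k subunit variances has bounded support
(|z| ≤ √(k−1)), so for small complexes the tail p-values deviate from
uniformity; the calibration test therefore uses complexes with ≥ 15
subunits, and small-complex within-dataset calls should be read as
rankings rather than exact probabilities. The cross-dataset test does not
suffer from this: each subunit's z-scores across datasets are compared to
the pooled z of its sibling subunits by a one-sided Welch t-test (variable
direction, matching the unidirectional hypothesis), BH-adjusted across all
tested (complex, subunit) pairs.

## Covariate effects

*Abundance.* Complex median abundance per sample (subunits quantified in
≥ 50% of samples, ≥ 5 eligible subunits) is compared between factor levels
with a two-sided pooled-variance t-test and Cohen's d (pooled,
n−1-weighted SD; signs follow male − female and high_fat − chow). Tests
pool across the other factor's levels — the two-group description of the
procedure implies pooled tests, and the balanced designs this targets make
pooling safe. BH across modules, significance at q < 0.01.

*Stoichiometry.* Per (complex, subunit), an additive two-factor model
(intercept + sex + diet on 0/1 codes, no interaction) is fitted by least
squares with casewise deletion, so each factor's contrast controls for the
other. Residual variances are moderated by an empirical-Bayes prior
(d0, s0²) estimated by method of moments on log s²: the log-variance mean
and spread are matched to the theoretical scaled-F moments via digamma /
trigamma identities, with d0 = ∞ (full shrinkage to s0²) when the observed
spread does not exceed the chi-square sampling floor. The estimator is
implemented in this package (`estimateVariancePrior()`) and verified to
1e-6 against limma's independent implementation in the test suite;
`priorDf = 0` recovers the ordinary t exactly. Moderated p-values are
BH-adjusted jointly across (complex, subunit, contrast).

Per-complex verdicts combine the component *q-values* by Fisher's method
(−2Σlog q, χ² with 2k df), as the procedure this reproduces prescribes.
Combining adjusted values is statistically unconventional — it is
conservative, since q ≥ p — so `useRawP = TRUE` offers the textbook
combination; the default stays faithful to the published recipe.

*Effect sizes.* The variance in a module's abundance (its median profile)
or stoichiometry (its complex-normalized subunit vectors) explained by sex,
diet, or both is estimated by ridge regression (penalty 1 on the binary
dummy slopes, intercept unpenalized, no standardization) under 10-fold
cross-validation. The global R² = 1 − SS_res/SS_tot is computed on pooled
out-of-fold predictions — more stable than averaging per-fold R² over
small folds — and the reported value is the median over 5 repeated
stratified fold assignments (and over subunit vectors for stoichiometry):
"median global R²" needs a definition of what the median runs over, and
this is ours. Folds are stratified by predictor-level combinations and
re-drawn (up to 100 times) if a training set would miss a level. Negative
R² is reported as-is; summaries additionally give max(R², 0) as a percent.
Significance comes from an empirical FDR: predictors are permuted across
samples, the full CV analysis re-run per permutation, and the plus-one
estimator (1 + #null ≥ observed)/(1 + n_perm) BH-adjusted across modules.
Pathways enter this stage only after a co-abundance pre-filter (empirical
p of the observed median pairwise r against within-protein-permuted
recomputations, BH, keep q < 0.1).

The ridge solution is computed in closed form from the penalized normal
equations; with at most two binary predictors this is exact and fast, and
it keeps the stated penalty convention (penalty on raw dummy slopes,
intercept free) explicit rather than delegated to a library with different
scaling conventions.

## The synthetic cohort generator

`generateCohort()` draws log2-scale abundances from a linear latent-factor
model. Each complex c has a shared factor
f_c = a_c·sex + b_c·diet + η_c with unit variance, where (a_c, b_c) encode
the configured fractions of f_c's variance attributable to sex and diet
(±½ codes, balanced crossed design). A subunit follows
y = μ + λ f_c + u·sex + v·diet + ε, with λ set so the shared factor
contributes the configured fraction of subunit variance
(`latentStrengthRange`, evenly spaced across complexes so strength maps
deterministically to complex index), ε Gaussian with `noiseSd` (0.3 log2
units by default, a typical inter-individual proteomic residual spread).
Designated *variable* subunits have λ shrunk (to 0 by default — fully
decoupled) and residual variance multiplied (4× by default); designated
stoichiometry-shift subunits receive u or v as a log2 shift on the second
factor level. Pathways reuse the construction at their own (weaker)
strength; background proteins are pure noise with matched marginal
variance; the interaction table lists within-complex pairs at score 0.9
plus equal numbers of background decoy pairs at 0.1. Dropout is completely
at random at `missingRate` (5% default). Replicate datasets share all
planted parameters and sample labels but draw independent η, ε and
dropout.

What the generator does *not* emulate: intensity-dependent (non-random)
missingness, heavy-tailed or batch-structured noise, shared peptides,
correlated background structure, or unbalanced designs. Passing tests on
this generator therefore demonstrate that the statistics recover the
structure they model — not that real cohorts satisfy the model; on real
data the AUCs and consistency correlations will be lower and the variance
fractions smaller.

`plantedR2()` is the oracle for effect-size recovery: it rebuilds the
generative components for a module and measures, on a large virtual cohort
(n = 100000), the population R² of the module's median-abundance response
on a predictor set. Because the median of the subunits retains a little
residual noise, the response-level fraction sits slightly below the
configured factor-level fraction; at high latent strength the two agree to
within ~0.01, which is how the recovery tests are calibrated.

## Worked example

```{r example, eval = FALSE}
sim <- generateCohort(cohortConfig(nSamples = 100, nComplexes = 50,
                                   nDatasets = 2, seed = 1))
res <- runPipeline("pipeline_out", config = cohortConfig(nDatasets = 2,
                                                         seed = 1),
                   seed = 1)
res$recovery$records      # AUC per dataset x category
head(res$landscape)       # stable/variable complex classes
head(res$componentCalls)  # cross-dataset variable-subunit calls
res$effectSizes$summary   # median R2 per readout x predictor set
```

## Numerical choices and problem sizes

Default parameters: min 5 quantified members per complex; min 6 shared
samples per correlation; trim 0.25; within-dataset component α 0.05 and
display |z| > 1.5; differential and stoichiometric significance q < 0.01;
pathway pre-filter q < 0.1; ridge penalty 1, 10 folds, 5 repeats; 1000
permutations/subsamples for the landscape and Mann–Whitney procedures.
Ties in correlation rankings take average ranks; ties in ROC thresholds
move together; zero variances yield z = 0 (not NaN); q-values of exactly 0
entering Fisher's method are clamped to the smallest positive double with
a warning.

The package's own validation runs on deliberately compact problem sizes —
cohorts of 50 complexes with 100–400 samples, 6 replicate datasets for
cross-dataset calls, 60–200 permutations for null bands — chosen so the
whole suite completes on a laptop while leaving the statistical margins
(AUC ≥ 0.8, recovery ≥ 90%, calibration within Monte-Carlo error) wide.

## Known limitations

* Identifier matching is exact-string; inputs must be pre-mapped to one
  identifier space (no ortholog or multi-ID collapsing).
* Within-dataset component p-values use a standard-normal reference for a
  bounded statistic; for complexes with < ~15 subunits they are
  approximate (see above). Cross-dataset calls are the robust readout.
* Fisher combination of q-values is conservative by construction.
* The landscape's quartile classes depend on the catalog analyzed;
  comparing classes between catalogs requires re-aggregation.
* No batch-effect modeling beyond quantile normalization, no
  interaction (sex × diet) terms, and no GO-enrichment stage.
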