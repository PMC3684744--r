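---
title: "Detecting dispersal syndromes and predicting dispersal from life-history traits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting dispersal syndromes and predicting dispersal from life-history traits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dispersyn)
```

## The problem

Dispersal — the movement of individuals that redistributes genes across a
landscape — drives metapopulation persistence, local adaptation and range
shifts, yet it is among the most expensive quantities to measure. For
butterflies, mark–release–recapture (MRR) surveys and allozyme-based
F_ST estimates cover a few dozen species, while life-history traits are
scored for entire faunas. Because dispersal co-evolves with demography,
specialization and behaviour, suites of traits ("dispersal syndromes")
carry enough signal to predict it. `dispersyn` implements that inference
chain: build the dispersal measurements, detect the syndromes, quantify
how well they predict, check that phylogeny can be ignored, and predict
dispersal for species never measured.

## The four dispersal measurements

Dispersal is not one number. The package distinguishes four elements,
each with its own construction and normalizing transform:

* **Mean dispersal distance** (km). MRR movement distances are fitted
  with a negative-exponential kernel, density `α·exp(−α·D)`. The maximum
  likelihood estimate is closed-form, `α̂ = 1/mean(D)`, so the kernel
  mean `1/α̂` *is* the sample mean — `fit_negexp()` asserts this identity
  rather than running an optimizer. Analysis scale: `ln x`.
* **Frequency of long-distance dispersal**. An inverse-power kernel
  `a·D^(−b)` (a Pareto law with tail index `b − 1` above a reference
  distance `d_min`) is fitted by the closed-form Pareto MLE
  `b̂ = 1 + n/Σ ln(Dᵢ/d_min)`. The element is the probability of moving
  beyond 5 km, computed by `tail_probability()` as the *integrated tail
  mass* `(5/d_min)^−(b−1)` — a probability of exceeding a distance is a
  tail integral, not the density evaluated at 5 km, which would carry
  units of 1/km and depend on the binning. Analysis scale: `log₁₀ x`.
  The reference distance `d_min` must be supplied by the user; there is
  no universally correct default, and the fitted tail is conditional on
  it.
* **Dispersal propensity**. One minus the resident fraction of
  recaptures, averaged over patches *unweighted* (`"averaged over
  patches of different size"` is read as a plain mean: each patch is one
  estimate of the same per-individual leaving probability, and weighting
  by recapture effort would let large patches dominate). Analysis scale:
  `−√x`.
* **Gene flow**. Stored as the raw fixation index F_ST; the analysis
  value is `1 − √F_ST`, which increases with gene flow. The square-root
  transform could equally be applied to the complement `1 − F_ST`
  (giving `1 − √(1 − F_ST)`); the source conventions are ambiguous, so
  both are implemented (`gene_flow_convention`), the first is the
  default, and the choice is recorded with the data rather than guessed
  per call.

All transforms are exactly invertible on their domains
(`dispersal_back_transform()`), which the test suite verifies to 1e−10.
Binned kernels (density per distance class) are supported by weighted
least squares on log density (`fit_kernel_binned()`); raw-distance MLE is
the default because its estimators are closed-form, unbiased (mean
distance) and have known sampling theory.

## Syndrome detection: two-stage exhaustive AICc selection

For one dispersal element, the response is its transformed value across
species and the candidates are 17 life-history traits plus
log wing length (wing length is log-transformed because size
relationships are allometric; it competes as an ordinary candidate, not
a forced covariate). Ordinal traits are coded as integer scores and
treated as numeric. Complete cases are taken over the response and *all*
candidates before the search, not per sub-model: information criteria
are only comparable between models fitted to the same observations.

**Curvature pre-screen.** Each non-binary candidate is regressed on the
response with centered linear and squared terms; a squared-term p-value
below 0.1 (pooling conventionally "significant" and "marginally
significant" curvature) flags the trait as potentially curvilinear. A
flagged trait contributes a *squared unit* on top of its linear unit.
The squared unit obeys marginality — it can only enter a model that
contains the linear unit — and the exhaustive search decides whether the
curvature survives. This matters for honesty at the screen's 10%
false-positive rate: a spuriously flagged trait costs nothing, because
the sub-models with only its linear part are still in the candidate set
and win on AICc. A retained linear+squared pair is reported as a single
second-degree polynomial unit.

**Stage one** enumerates every subset of main-effect units with at most
`max_coef = 8` slope coefficients (the cap that prevents saturation at
n ≈ 25–29) and ranks them by AICc with the small-sample correction,

&nbsp;&nbsp;&nbsp;&nbsp;AICc = −2ℓ + 2p + 2p(p+1)/(n−p−1),

where `p` counts intercept, slopes and the residual variance, and ℓ is
the Gaussian log-likelihood at the MLE variance. The cap counts slope
coefficients only; it is configurable because published applications of
this procedure show retained models whose printed coefficient rows
exceed eight, so the original counting convention is evidently looser
than ours.

**Stage two** pools the variables of every stage-one model within
ΔAICc ≤ 2 of the best ("the variables retained in the top-ranked
models", plural — the union, not just the single best model), adds all
pairwise interactions among them (an interaction may only enter with
both main effects present), and searches again under the same cap.

**Final choice.** Among stage-two models within ΔAICc ≤ 2, the one with
the highest R² is retained — the member of the statistically
indistinguishable set that captures most of the deviance, appropriate
when the goal is prediction. Ties are broken deterministically: higher
adjusted R², fewer coefficients, lexicographic term order.
`term_stability()` reports, for each term, the fraction of top-set
models containing it, so a retained term can be checked against the
alternative models of similar fit.

### Numerical choices

* Quadratic units use raw centered powers (`x − x̄`, `(x − x̄)²`), not
  orthogonal polynomials; fits and R² are identical, and the centering
  is stored so predictions for new species reuse the training
  parameterization.
* The all-subsets search solves each sub-model from Cholesky factors of
  the full candidate cross-product matrix; a testthat invariant checks
  every enumerated model's AICc against an independent `lm()` refit to
  1e−8. Singular sub-models are dropped; the exposed single-model fitter
  errors instead, naming the collinear columns.
* Residual sums of squares below 1e−12 × TSS are floored there: with
  noise-free data the RSS of every model containing the true terms is
  float noise (~1e−28), and without the floor the AICc and R² ordering
  among perfect fits would be decided by that noise. With it, perfect
  fits tie exactly and the parameter penalty decides — the smallest true
  model wins, which is the behaviour the recovery tests assert.
* Enumeration order is deterministic (depth-first, mains before
  dependent units), so results are exactly reproducible.

## Quality assessment by cross-validation

`cross_validate()` draws random 75–25 partitions of the species
(training size `round(0.75·n)`, half-up — 22 of 29, matching the 19–22
training / 6–7 test split the design targets), refits the term set on
the training partition and predicts the held-out species. Over 100
partitions (default) each species accumulates a mean prediction and a
standard error from the partitions that held it out; species never held
out (possible at small n) are reported with missing predictions.
Partitions whose training design is rank-deficient are redrawn and
counted. Partitioning is uniform random without stratification.

Two metrics summarize a model, both computed on the transformed
(analysis) scale where the models live:

* **rightness** — the OLS slope of observed on mean predicted values,
  intercept included (the metric is defined as the plain regression
  slope even where a through-origin line is also plotted); ideally +1;
* **imprecision** — the mean absolute difference between observed and
  predicted values; for the two scale-dependent elements (mean distance,
  long-distance frequency) each difference is divided by the observed
  value (`relative = TRUE`), making the metric invariant to rescaling.

`assess_performance()` runs 20 independent cross-validations (fresh
partitions nested within each repeat — the repeats are not a subset of
the partitions) and reports mean ± SE over repeats.
`compare_models()` contrasts a syndrome model with the wing-size-only
reference — a GLM with log wing length as sole regressor, refit per
partition under exactly the same protocol — reporting the *gain in
rightness* (difference of slopes), the *gain in precision* (ratio
reference/trait imprecision, > 1 meaning the trait model is more
precise) and p-values from a regression of the per-repeat performance
values on the model-type indicator.

## Relative importance of traits

`r2_partition()` decomposes the chosen model's R² by the
Lindeman–Merenda–Gold rule: the contribution of a regressor unit is its
average R² increment over all orderings of the units. Contributions are
non-negative and sum exactly to the full R² (a telescoping identity the
tests assert to 1e−10). For up to 10 units the subset-weighted exact
formula is used (2^p sub-models instead of p! orderings); its
equivalence with a literal factorial-ordering oracle is itself a test.
Two grouping conventions exist because published tables are ambiguous
about whether polynomial halves carry separate contributions:
`mode = "unit"` (default) treats a polynomial pair or an interaction as
one unit; `mode = "coefficient"` orders individual design columns.

## The phylogenetic check

Comparative data may be non-independent through shared ancestry.
`pgls_fit()` refits a term set by generalized least squares with
residual covariance `V(λ)`: the Brownian-motion covariance of the tree
(shared branch lengths) with off-diagonals multiplied by Pagel's λ,
estimated by maximum likelihood on [0, 1] via a 16-point grid pre-scan
(to dodge local optima) plus golden-section refinement; the profile is
asserted to dominate a λ grid to optimizer tolerance. When the λ = 0
test does not reject, plain GLMs over species are justified.

The λ = 0 test needs care because the null lies on the parameter
boundary. Two corrections are applied: the reference distribution is the
half-and-half mixture of χ²₀ and χ²₁, and the likelihood ratio is
computed from the *restricted* (REML) profile of λ. The second is not
cosmetic: with the full ML profile the fitted intercept absorbs part of
the shared phylogenetic covariance, the λ-score at zero acquires a
negative mean, and the boundary mass of λ̂ sits near 0.8 rather than the
asymptotic 0.5 — the test then rejects a true λ = 0 at roughly 2%
instead of 5%, and the deficit does not shrink with tree size (checked
at 64–256 tips). With the REML profile the empirical size is within
Monte-Carlo error of nominal (4–5% over 400 simulations in the
acceptance run). Point estimates of λ and the coefficients remain plain
ML.

## Prediction for unmeasured species

`predict_species()` applies a fitted model to every species of a trait
table with complete values for the model's traits, then back-transforms
with element-specific truncation: long-distance frequency is clipped
into (0, 1], propensity and gene flow into [0, 1]; mean distance needs
no truncation because the log-scale back-transform is always positive.
Truncation events are flagged. Predictions are only trusted by default
for species whose retained-trait values fall inside the closed
[min, max] interval observed in the training species
(`applicability_mask()`): the shape of a dispersal–trait relationship is
unknown outside the fitted range, and min–max per retained trait is the
simplest formalization of "comparable trait values". Out-of-range
species keep their transformed-scale prediction but have the
natural-scale value suppressed unless `extrapolate = TRUE`.
`summarize_distribution()` reports means, extremes and quantiles —
type-7 linear interpolation of order statistics, stated explicitly
because statements like "90% of species are predicted below x" depend on
the quantile rule — plus kernel densities for plotting.

## The synthetic-data generator

Real trait databases and dispersal compilations are not redistributable,
so the package ships a generator that emulates their structure:

* `simulate_trait_table()` draws each trait independently and uniformly
  within its defined range (continuous traits uniform over the interval;
  ordinal and binary traits uniform over their levels). Defaults are the
  documented trait ranges (e.g. voltinism 0.5–3 generations/yr, ovigeny
  index 0–1, wing length 11–37.5 mm).
* `true_model()` + `simulate_responses()` build a transformed-scale
  response `intercept + Σ coef·term + N(0, noise_sd)` on internally
  standardized traits, so coefficients are per-SD effects and "an effect
  of ≥ 1 SD" means `|coef| ≥ 1`. The raw value is the inverse transform,
  clipped into the element's domain with clipping recorded.
* `simulate_mrr_distances()` draws exponential or Pareto distances;
  `simulate_residency()` draws binomial patch counts;
  `simulate_tree_and_trait()` grows a pure-birth tree and draws one
  trait from the λ-rescaled Brownian covariance.

What the generator does **not** emulate: trait–trait correlation (traits
are drawn independently by default so that recovery tests are
interpretable — an optional override is the trait-range argument, and
correlated designs can be built by hand), empirical trait distributions
(real scores are not uniform), measurement error in the dispersal
ingredients, and non-Gaussian residual structure. Passing recovery tests
therefore demonstrates that the machinery is correct, not that real
butterfly data would yield syndromes of any particular strength.

## Study conditions used by the tests and the acceptance run

The recovery fixture plants 2 linear terms with ±1 SD effects among 10
candidate traits at n = 29 species and residual SD 0.25 on the
transformed scale — the sample size and noise regime of a realistic
single-element analysis. Kernel recovery uses 200 samples of n = 500
exponential distances at α = 5/km; the cross-validation comparison runs
50 replicates of 10 repeats × 50 partitions each; PGLS calibration uses
400 null simulations on 48-tip trees and 100 Brownian simulations on
64-tip trees; the R² decomposition is checked against the factorial
oracle at p ≤ 6. These sizes keep every check exact or tightly bounded
while the full suite runs in a few minutes.

## Known limitations

* The selection procedure is exhaustive: 18 candidates under a cap of 8
  enumerate ~2×10⁵ main-effect models, which is seconds here, but the
  stage-two space grows quickly with the pooled-variable count; very
  permissive `delta` windows on noisy data can make stage two large.
* The highest-R² rule inside the AICc window deliberately trades
  parsimony for deviance captured; at n ≈ 29 the chosen model usually
  carries hitchhiking terms beyond the true ones (the cross-validation
  stage exists precisely to price that in).
* AICc comparability forces complete cases over all candidates; with
  patchy trait coverage this can discard species that some sub-models
  could have used.
* Propensity averaging ignores patch-size effects by design; kernels are
  limited to the two classical families; no detectability correction for
  MRR is attempted.
* The λ test is calibrated for one covariance parameter on one tree;
  simultaneous selection over traits and λ is not performed (λ is a
  preliminary check, mirroring the intended workflow).
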