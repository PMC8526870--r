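---
title: "Normative modelling of neonatal cortical development: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Normative modelling of neonatal cortical development: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(corticonorm)
library(dplyr)
```

This vignette documents the statistical machinery in `corticonorm`: the
generative model behind the synthetic cohorts, the Gaussian-process
normative model and its calibration, the permutation inference, the
age-prediction stage, and the design decisions taken where several
reasonable choices existed.

## The scientific setting

Between about 37 and 45 weeks postmenstrual age (PMA), the cortex expands
and differentiates rapidly: surface area grows fastest of all measures,
thickness increases, diffusion anisotropy in the cortical plate falls as
dendritic arbours ramify, and neurite orientation dispersion rises. A
normative model captures these trajectories in term-born infants and asks,
for each preterm infant scanned at term-equivalent age, *where and by how
much does this individual deviate from typical development?* The unit of
analysis is a parcel–metric cell: 286 approximately equal-sized surface
parcels (143 per hemisphere) by eight metrics — FA, MD (μm²/ms), ODI, fICVF,
cortical thickness (mm), surface area (mm², summed per parcel where all
other metrics are parcel means), curvature and sulcal depth.

## The synthetic cohort generator

Real cohort data cannot ship with a package, so every stage is exercised
against simulated cohorts with known ground truth. The generator emulates
the statistical structure the analysis assumes, not the imaging physics:

```
value = baseline[m, r] + slope[m, r] · (PMA − 40) + sex_effect[m] · sex
      + preterm_effect[m, r] · g(GA) · I(preterm) + extreme offset + noise
```

* **Parcellation.** Seeds are placed on a unit hemisphere by farthest-point
  sampling (the seven region anchors — frontal, parietal, temporal,
  occipital, insula, cingulate, somatosensory — are always retained so every
  region is represented), approximating the centroids of an equal-area
  Voronoi decomposition; the right hemisphere mirrors the left.
* **Demographics.** Term GA at birth is drawn from a truncated normal on
  [37, 42.14] weeks, preterm GA on [23, 36.86]; PMA at scan comes from a
  common window ([37, 45.14], never before birth) independent of group, so
  the groups are age-matched at scan; 46% of infants are female; 18-month
  composite outcome scores are normal with mean 100 and SD 15 and, by
  default, independent of everything else — deliberately, so the
  outcome-association stage has a testable null.
* **Prematurity scaling.** Group effects scale linearly with the degree of
  prematurity, `g(GA) = max(0, 37 − GA)/14`: a 23-week infant receives the
  full configured effect, a term infant none. A linear ramp is the simplest
  shape consistent with graded GA associations without inventing a
  published dose–response curve. PMA is centred at 40 weeks, the midpoint
  of the scan window, so baselines are interpretable.
* **Default effect pattern** (qualitative late-third-trimester physiology):
  surface area grows everywhere and fastest (+4 mm²/week on a 120 mm²
  baseline), thickness +0.015 mm/week on a 1.1 mm baseline (the neonatal
  cortical sheet is only about 1.1 mm thick), FA falls posteriorly, MD falls
  centrally/insular, ODI rises everywhere, fICVF rises anteriorly/insular,
  sulcal depth deepens in the cingulate, curvature is static. Preterm birth
  raises MD and lowers fICVF posteriorly, thickens anterior cortex and
  raises FA / lowers ODI in the insula. No per-parcel means or SDs of the
  real metrics are published for this design, so baselines and noise SDs
  are plausible, configurable values — not calibrated to any cohort — and
  what passing tests demonstrate is correctness of the machinery under the
  generator's assumptions (linearity, Gaussian noise, independence across
  cells), not fidelity to real dHCP data, which are spatially smoother,
  heteroscedastic and non-Gaussian in the tails.
* **Extreme deviations.** With probability 0.10 per (subject, metric), a
  preterm infant receives an offset in 1–3 random parcels, with magnitude
  uniform in 4–8 local noise SDs (the lower bound must exceed the 3.1
  detection threshold) and sign following the metric's configured preterm
  direction with probability 0.75 — both positive and negative individual
  deviations occur, as observed empirically. Every injection is recorded in
  a ground-truth table for recovery tests.
* **Bounded metrics.** FA/ODI/fICVF are clipped to [0, 1] post hoc and
  MD/thickness/SA floored at a tiny positive value; clip counts are
  returned. Defaults keep baselines many SDs from the bounds, so clipping
  is essentially never triggered under default noise.

## The Gaussian-process normative model

Each parcel–metric cell gets an independent GP regression of the feature on
standardized PMA and binary sex with covariance `k(x, x') = σ_r²
exp(−‖x−x'‖²/2ℓ²) + σ_l² x·x' + σ_n² δ`, hyperparameters maximising the log
marginal likelihood. Independence across the 8 outputs is the minimal
reading of a per-cell Z-score analysis; no coregionalization structure is
assumed (and none is claimed by the design this package implements).

Numerical choices:

* Outputs are standardized per cell; PMA standardized on training data; sex
  stays 0/1. Optimization runs in log-parameter space with analytic
  gradients (L-BFGS-B, bounds 1e-10–1e3 on variances), one deterministic
  start (equal variance split, unit lengthscale) plus `restarts − 1`
  randomized starts with lengthscales around 0.5–2 covariate SDs; the best
  run is kept and must beat every start's likelihood. Five restarts are the
  default; large simulation studies in the tests use two, which changes
  fitted likelihoods negligibly on these smooth one- and two-dimensional
  problems.
* The RBF lengthscale is bounded below at 0.1 standardized covariate units.
  Below the typical covariate spacing the RBF kernel becomes
  indistinguishable from a second white-noise component — a ridge in the
  marginal likelihood on which the optimizer can land anywhere, with
  pathological predictive behaviour (the smoother interpolates noise and
  its effective dof approaches n). The bound is an identifiability
  constraint, not a smoothness prior: 0.1 standardized units is far below
  the scale of any developmental trend the model is meant to capture.
* Cholesky factorisation with jitter escalation 1e-8 → 1e-4 of the output
  variance; a cell that still fails is flagged and excluded downstream
  (atypicality denominators still count it, as a normative parcel).
  Constant outputs fall back to a noise-only model.
* **Predictive variance includes the noise term**, so Z-scores for *new
  observations* are calibrated; without it, every slightly noisy infant
  would appear extreme.
* **Degrees-of-freedom correction and studentization.** Plug-in ML
  predictive variances are optimistic in two distinct ways, and the package
  applies the classical remedy for each, exactly as for externally
  studentized residuals in linear regression. First, the scale: the fitted
  smoother absorbs `ν = tr(S)` degrees of freedom, so predictive variances
  are inflated by `n / (n − ν)` — the GP analogue of dividing residual sums
  of squares by `n − p` instead of `n`; without it, pooled hold-out Z
  variances sit near 1.04 instead of 1.00 on 150 training subjects. Second,
  the shape: a residual divided by an *estimated* scale is t-distributed
  with `n − ν` degrees of freedom, not normal, so at `|Z| > 3.1` the
  nominal 0.00194 two-sided tail is overshot by ~15% even with an unbiased
  scale. [compute_z_scores()] therefore maps the studentized ratio through
  its t reference distribution onto the standard-normal scale
  (`Z = Φ⁻¹(F_t(ratio))`), after which the 3.1 threshold carries its
  nominal p < 0.001 meaning. Both steps can be disabled
  (`df_correction = FALSE`, `calibrate = FALSE`) to obtain the plain
  plug-in posterior and raw ratios.
* Z-scores are oriented as `(observed − predicted)/SD`, so positive Z means
  a value above the normative curve — the orientation under which a group
  with elevated MD shows extreme *positive* MD deviations. The reverse
  orientation is available via `sign = "pred_minus_obs"` for compatibility
  with the difference written the other way round.
* Predictions warn (never refuse) when PMA falls more than 1 week outside
  the training range: extrapolated normative curves remain well-defined but
  their variances grow, which is exactly what the user should see.
* `|Z| = 3.1` exactly is classified normative — the strict inequality
  reading of "extreme means beyond 3.1".

The 75/25 train/hold-out split of the term sample is stratified by PMA
quartile with largest-remainder allocation, so the hold-out count equals
`round(0.25 n)` exactly and train and hold-out age distributions match; one
shared split serves both the normative and the age-prediction stage.

## Permutation inference

Per-cell GLM t-statistics for one tested column (group indicator, PMA, GA,
an outcome score, or the group × centred-PMA product) with nuisance
covariates are referred to a max-statistic permutation null under the
Freedman–Lane scheme: data are residualized on the nuisance, residuals are
permuted, and the full model is refitted per permutation. Each permutation
records the maximum |t| across **all parcels × 8 metrics**, and both
one-sided contrasts are referred to this single max-|t| distribution — one
distribution, jointly controlling the family-wise error across parcels,
modalities and contrasts, and cheaper than two separate runs. p-values use
the +1/+1 convention (`p = (1 + #{max ≥ t}) / (1 + n_perm)`), so they are
never zero and the test is exact under exchangeability. The t-statistics
share their degrees of freedom across modalities, which is what makes the
joint maximum exchange-comparable. Pearson r reported alongside is the
simple bivariate correlation between tested covariate and feature (a
partial-r option exists). A zero-residual cell returns a capped sentinel
t of 1e6 rather than infinity. A minimum of 100 permutations is enforced —
below that the tail of the max distribution is too unstable to report.

## Age prediction

A random forest predicts PMA at scan from all parcel–metric columns with
the fixed configuration 1000 trees, depth 35, minimum leaf size 2 and all
features considered at every split ("all" being the historical regression
reading of `max_features = "auto"`); hyperparameter search is deliberately
out of scope, these values are the tuned optima of the design this package
follows. Regression-to-the-mean bias is removed with the error-in-variables
orientation: fit `raw = a + b · true` on training predictions, apply
`corrected = (raw − a)/b` to hold-out predictions (the alternative
`true ~ raw` orientation is available). On training data the corrected
predictions regress on true age with exactly unit slope and zero intercept
— an algebraic identity the tests verify to 1e-8. Hold-out performance is
summarized as MAE, MSE, Spearman ρ (average ranks for ties) and R² (one
minus the residual-to-total sum-of-squares ratio). Feature importance is
training impurity importance; the top `ceil(0.10 · n_features)` features
(ties broken by stable feature order) are counted per metric.

## Outcome associations

Whole-cortex atypicality indices contain many zeros and ties, so rank
statistics are used throughout: Kendall τ-b (tie-corrected; exact p where
sample size and ties permit, otherwise a tie-corrected normal
approximation) against GA at birth and outcome scores, and two-sided
Mann–Whitney U for group contrasts. Benjamini–Hochberg FDR is applied
within each analysis block — metrics × index signs × outcomes for a given
covariate family — mirroring how such analyses are reported. Fully tied
comparisons are returned as missing (τ) or p = 1 (U) with a reason rather
than NaN.

## Problem sizes in the test-suite simulation studies

The heavy properties are checked at sizes chosen to make Monte-Carlo error
small relative to the tested bands while staying single-CPU friendly:
Z calibration on 150 training / 50 hold-out term subjects at 250 parcels
(10⁵ pooled cells); family-wise error over 200 null replicate cohorts of
40 subjects × 80 parcels at 500 permutations; recovery of injected extremes
on 100 + 60 subjects × 40 parcels; group-effect detection (1.5 SD in 20
parcels) on 100 + 40 subjects at 1000 permutations; the interaction null
over 20 replicate cohorts. Permutation counts of 500–1000 in these studies
stand in for the 10,000 a full analysis would use; the max-statistic tail
is stable at these sizes for the α = 0.05 decisions being tested.

## Known limitations

* Cells are modelled independently; spatial correlation between parcels and
  correlation between metrics are neither modelled nor exploited. Overlap
  maps inherit this: they describe marginal prevalence, not joint patterns.
* The generator's noise is Gaussian and homoscedastic within cell; real
  cortical metrics are not, so calibration results transfer to real data
  only approximately.
* The GP is exact (dense Cholesky), fine for hundreds of training subjects
  per cell but not for tens of thousands.
* Atypicality indices treat failed-fit parcels as normative, keeping the
  denominator at the full parcel count; with many failed cells the indices
  would be biased toward zero (failure counts are reported).
* No longitudinal modelling: one scan per subject.
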