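---
title: "Modelling temperature and fasting plasma glucose: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling temperature and fasting plasma glucose: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the exposure model, the additive model for fasting plasma glucose (FPG),
the counterfactual temperature adjustment, the synthetic-data generator
used to validate all of it, and the numerical decisions that a maintainer
would otherwise have to reverse-engineer from the code.

## The problem

FPG measured in a cross-sectional survey carries a signature of the
weather on (and shortly before) the survey day: cold ambient temperature
is associated with higher FPG, plausibly through cold-induced changes in
insulin sensitivity and counter-regulatory hormones. A survey spanning
seasons or climate zones therefore mixes physiological states, and
quantities defined by a fixed glycemic threshold — type 2 diabetes (T2DM)
prevalence at FPG ≥ 7.0 mmol/L, glycemic control at FPG < 7.0 mmol/L —
inherit that bias. The package estimates the temperature–FPG relationship
per diabetes subgroup and re-expresses prevalence and control rate at
common reference temperatures.

## Exposure model

Daily station meteorology is interpolated to each participant's
residential district centroid by inverse distance weighting:
prediction = Σ wᵢ vᵢ with wᵢ ∝ dᵢ⁻ᵖ and Σ wᵢ = 1.

* **Distance** is great-circle (haversine) distance in km
  (`geosphere::distHaversine`). Over a province several degrees wide,
  planar lon/lat distance is anisotropic; the spherical metric is not.
* **Power** defaults to p = 2, the conventional IDW choice; it is a
  configuration parameter, not a fitted quantity.
* **Exactness**: a target within 1 m of a station returns that station's
  value, making the interpolator exact at stations and every prediction a
  convex combination of the day's station values.
* **Target**: the district centroid, matching how residential exposure is
  assigned when street addresses are unavailable. A full raster is an
  unnecessary intermediate for this pipeline and is not built.
* **Altitude** is deliberately not an interpolation covariate; the
  exposure surface is purely horizontal.
* **Cross-validation** partitions *stations* (not station-days) into k
  folds — holding out single station-days would leak a station's own
  highly autocorrelated series into its prediction. Accuracy is reported
  per variable as RMSE and as R², defined as the squared Pearson
  correlation between held-out observations and predictions; this
  definition is robust to a calibration offset and is recorded in the CV
  report alongside the fold count and seed. R² is undefined (NA) for a
  zero-variance field.
* **Lags**: lag ℓ exposure is the single interpolated value ℓ calendar
  days before the survey date (lag 0 = survey day). No moving averages are
  formed; sensitivity across lags 0–6 is a set of separate single-lag
  models.

## The additive model

For subgroup m (total population, NFG, known T2DM, newly detected T2DM):

FPG_im = β₀m + s(temp, k) + s(humidity, 3) + s(age, 3) + s(BMI, 3) +
categorical covariates + ξ_district + ε_im

* Smooths are penalized cubic regression splines (`mgcv`, `bs = "cr"`).
  The basis dimension k = 3 for temperature is read as the spline's basis
  dimension (maximum ~2 effective degrees of freedom after the sum-to-zero
  constraint, less under penalization); k is selectable over {3, 4, 5} by
  AIC via `select_basis_dimension()`. A "graphic smoothness" side
  criterion is replaced by the objective AIC rule so that selection is
  reproducible.
* The district random intercept is realized as a ridge-penalized district
  factor, `s(district, bs = "re")`, with its variance estimated by REML —
  the standard mixed-model-as-smooth equivalence. REML is also the
  smoothing-parameter criterion for all other terms; for degenerate
  responses (zero variance) the fitter falls back to GCV.
* Covariates constant within a subgroup (hypoglycemic-medicine use among
  NFG or newly detected participants, by construction) are dropped with a
  notice rather than producing a rank-deficient fit.
* Missing model variables are handled by complete-case analysis with a
  logged count; no imputation.
* Exposure-metric selection (`select_exposure_metric()`) fits all
  candidates (tmean/tmin/tmax × lags) on the *identical* row set —
  complete cases across every candidate column — because AIC values on
  different data are not comparable. Ties are broken by declared candidate
  order, with a message.

### Curves, anchors, contrasts

The fitted temperature smooth is evaluated on a 0.1 °C grid over the
observed exposure range. The anchor t\* is the grid argmin; ties are
broken toward the warmer temperature, so a flat warm tail anchors at its
warm end. The curve is reported as ΔFPG(t) = s(t) − s(t\*), with
pointwise 95% CIs from the linear-contrast variance cᵀΣc, where Σ is the
coefficient covariance of the fit and c the difference of basis rows —
hence ΔFPG(t\*) = 0 with a zero-width interval, and the curve is invariant
to vertical shifts of the raw smooth. Contrasts between two temperatures
use the same construction; `contrast_ci_sim()` provides a
coefficient-resampling cross-check (10,000 multivariate-normal draws)
that the test suite requires to agree with the analytic interval within
5% of its width. Contrast endpoints requested outside the observed range
are an error at the model level; the pipeline clamps its standard
reporting points (5, 19, 30 °C) to each subgroup's observed range and
records the actual endpoints.

The cold reference is exposed as a parameter (`contrast_cold`, default
5 °C): source reports of this design vary between 4 and 5 °C for the cold
end, and the package does not attempt to resolve that; 5 °C is the
default because it matches the tabulated contrasts.

### Interaction test

`test_interaction()` compares a total-population model with one shared
temperature smooth plus subgroup main effects against one that adds
ordered-factor difference smooths of temperature by subgroup. By default
the spline bases are unpenalized (`fx = TRUE`, fixed degrees of freedom),
so the nested-model F test is exact under the Gaussian model — this is
what makes the null-calibration property testable (rejection rate ≈ 5% at
α = 0.05). A penalized variant (approximate likelihood-ratio comparison,
method = "ML") is available via `fx = FALSE`.

## Temperature adjustment

For participant i in subgroup m observed at temperature t and reference j:
ΔFPG_ijm = curve_m(t) − curve_m(j) (linear interpolation on the curve
grid, temperatures clamped to the grid range), and
FPG_2ijm = FPG_1im − ΔFPG_ijm. Adjusted values below 0 are floored and
counted. Adjustment uses curve point estimates only — no propagation of
curve uncertainty into the rates — matching how such adjusted rates are
conventionally presented.

Two case-counting rules are implemented for prevalence:

* `reclassify` (default): known patients are always cases; *all*
  undiagnosed participants — originally NFG or newly detected — are
  re-evaluated against 7.0 mmol/L on their adjusted FPG, each using their
  own subgroup's curve. This is the only rule under which warm-reference
  prevalence can fall below the crude rate, which is the observable
  signature of this family of adjusted estimates.
* `literal`: every originally newly detected participant stays a case and
  only the NFG subgroup is re-evaluated — the strict reading of the
  case-count definition. The rules agree whenever no adjusted FPG crosses
  the threshold; both are exposed because the definitions in circulation
  are contradictory on this point, and neither is presented as uniquely
  correct.

Control rate uses known patients only (N₂j/N₄), so the question of
removing reclassified newly detected participants from its denominator
does not arise. Useful identities, enforced by tests: adjusting everyone
to their own survey-day temperature reproduces observed FPG and crude
rates exactly; prevalence never falls below the known-patient share; a
monotone-decreasing known-T2DM curve forces a nondecreasing control rate
in the reference temperature; within a subgroup surveyed at one
temperature, adjustment is a rank-preserving rigid shift.

## The synthetic-data generator

The generator emulates the structure of a multi-season, multi-district
southern-China survey:

* **Weather**: stations uniform in a bounding box; daily mean temperature
  = annual mean + seasonal cosine (warm peak in mid July) + linear
  spatial gradient + Gaussian station-day noise; tmin/tmax by folded-
  normal spreads so tmin ≤ tmean ≤ tmax always; humidity tracks the
  deterministic part of temperature (monsoon-like warm-humid coupling,
  default 1%/°C) plus noise, clamped to [0, 100]. Defaults (mean 19 °C,
  amplitude 10 °C, 86 stations) give an October–May window spanning
  roughly 5–31 °C of daily means.
* **Cohort**: districts at random centroids; each participant gets a
  district, an October–May survey date (full-year generation behind a
  flag), demographics and lifestyle covariates with survey-like marginal
  distributions, and a subgroup drawn from the mixture (90.6% NFG / 3.5%
  known / 5.9% newly detected by default). FPG is assembled additively:
  subgroup baseline + polynomial temperature effect f_m(t) + linear
  covariate effects + Gaussian district intercept + Gaussian residual.
  The exposure entering f_m is the IDW temperature at the district
  centroid on the survey date — the same quantity the fitting pipeline
  later reconstructs, so exposure truth and assigned exposure agree to
  machine precision.
* **Label consistency**: by default residuals are rejection-sampled so
  NFG participants end below 7.0 mmol/L and newly detected at or above it
  (their labels then satisfy the WHO rule by construction); known
  patients are unconstrained and get a physician-diagnosis flag and a
  73.8% medicine-use rate. Recovery simulations that need unbiased
  Gaussian residuals disable the enforcement (`enforce_threshold =
  FALSE`), because truncation would bias planted-contrast recovery.
* **Curves**: f_m(t) is a polynomial of degree ≤ 3 on a stated range, so
  planted contrasts are known in closed form (`truth_contrast()`).
  Defaults: downward parabolas anchored at 30 °C with f(5) − f(30) = 0.10
  (NFG) and 1.34 mmol/L (known), and a U-shape with vertex 19 °C and
  f(5) − f(19) = 0.71 mmol/L (newly detected).
* **Reproducibility**: every random component (station placement,
  temperature noise, spreads, humidity, mixture, covariates, district
  intercepts, residuals, medicine use) draws from its own stream derived
  from the master seed, so changing e.g. the station count does not
  perturb cohort draws, and identical specs are byte-identical.

**What the generator does not emulate** — and hence what passing tests do
*not* establish about real data: FPG is Gaussian around its mean (real
FPG is right-skewed, especially among diabetic patients, which depresses
e.g. synthetic control rates relative to published ones); covariates are
mutually independent and independent of temperature (no confounding);
participants sit exactly at district centroids; there is no measurement
error in exposure beyond interpolation; household sampling design and
weights are out of scope. Published magnitudes that depend on the real
FPG distribution (adjusted prevalence of 8.9–9.7%, control rates of
33–55%) are therefore not reproduction targets; the validation battery
targets structure (coverage, anchors, monotonicity, identities) instead.

## Validation battery and problem sizes

The test suite's heavier checks, with the sizes chosen for them:

* **Contrast recovery / CI coverage**: linear planted effects with
  cold–warm contrasts 0.10 and 1.34 mmol/L; 100 replicates per scenario
  (200 total) at n = 5,000, 15 districts, residual SD 0.8. Linear truths
  are used deliberately: they lie in the span *and* the penalty null
  space of the cubic regression spline basis, so coverage of the analytic
  CI is tested without confounding from basis-approximation bias.
  Pooled coverage is required to lie in [90%, 99%].
* **Anchor location**: n = 20,000; U-shaped truth with vertex 19 °C,
  basis dimension chosen by AIC over {3, 4, 5} (at k = 3 the quadratic is
  only approximable and the vertex estimate degrades; AIC reliably moves
  to a basis that resolves it), anchor required within 1 °C; monotone
  truth anchors at the warm boundary.
* **Interaction calibration**: 400 null replicates at n = 900, rejection
  rate at α = 0.05 required in [2%, 8%]; power check with a 10-fold slope
  difference at n = 20,000 requires p < 0.001.
* **Validation climate**: these simulations use a winter-cold variant of
  the weather field (annual mean 19.6 °C, amplitude 14.6 °C) whose
  October–May daily means span 5–30 °C, so the 5 °C and 30 °C evaluation
  points always lie inside the observed exposure range.

All simulations are seeded; the acceptance script derives every stream
from its single `--seed` argument.

## Known limitations

* The curve CIs are conditional on the selected smoothing parameters
  (standard for REML-fitted additive models); selection uncertainty over
  k and exposure metric is not propagated.
* Adjusted rates carry no uncertainty intervals by default (point-curve
  adjustment); `contrast_ci_sim()` covers curve uncertainty only.
* IDW with power 2 and no elevation covariate is a deliberate floor, not
  a ceiling, on exposure-model sophistication — no kriging or thin-plate
  alternatives are provided.
* `classify_t2dm()` flags undiagnosed participants reporting
  hypoglycemic-medicine use as unclassifiable (NA) and `classify_cohort()`
  excludes them with a logged count: they fit neither the NFG definition
  (which excludes hypoglycemic use) nor the newly-detected one. The choice
  is reversible by reassigning the NA labels before analysis.
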