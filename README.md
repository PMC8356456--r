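# thermoglyc

Ambient temperature shifts fasting plasma glucose (FPG): population surveys
measure higher FPG in cold months than in warm ones, so a diabetes survey
run in winter in a cold district and one run in spring in a mild district
are not directly comparable. `thermoglyc` implements the full inference
chain needed to quantify and remove that effect in cross-sectional survey
data:

1. **Exposure surface** — daily weather-station records are interpolated to
   residential districts by inverse distance weighting (IDW, great-circle
   distances, power 2), validated by k-fold cross-validation with folds
   drawn over stations, and attached to participants as single-day lag 0-6
   exposures.
2. **Cohort building** — participants are classified by WHO 2006 criteria
   into normal fasting glucose (NFG, undiagnosed and FPG < 7.0 mmol/L),
   known T2DM (physician-diagnosed, any FPG) and newly detected T2DM
   (undiagnosed, FPG >= 7.0 mmol/L; optionally also 2-h glucose >= 11.1),
   with Table-1 style descriptives and monthly FPG/temperature series.
3. **Temperature-response model** — per subgroup *m*, a Gaussian additive
   mixed model

   *FPG<sub>im</sub>* = β<sub>0m</sub> + s(temp, k=3) + s(humidity, k=3) +
   s(age, k=3) + s(BMI, k=3) + covariates + ξ<sub>district</sub> +
   ε<sub>im</sub>

   with penalized cubic regression splines, categorical fixed effects
   (sex, education, career, activity, sedentary time, smoking, drinking,
   hypoglycemic-medicine use) and a district random intercept, fitted by
   REML with `mgcv`. Exposure metric and basis dimension are selected by
   AIC. The fitted temperature smooth is re-expressed as the FPG difference
   ΔFPG(t) from the minimum-FPG (anchor) temperature t\*, with analytic
   pointwise CIs, contrasts between any two temperatures, and a
   temperature-by-status interaction test.
4. **Temperature adjustment** — each participant's FPG is shifted along
   their subgroup's curve to a reference temperature *j*:
   FPG<sub>2ijm</sub> = FPG<sub>1im</sub> − ΔFPG<sub>ijm</sub>; prevalence
   (cases / all participants, known patients always cases, undiagnosed
   participants re-evaluated at 7.0 mmol/L) and glycemic control rate
   (known patients with adjusted FPG < 7.0 / all known patients) are then
   recomputed at references 5-30 °C.
5. **Synthetic-data generator** — seasonal station weather fields and
   survey cohorts with known ground truth (subgroup mixture, polynomial
   temperature curves, covariate effects, district intercepts), so every
   stage is testable end to end without access to confidential survey data.

The package is aimed at epidemiologists analysing glycemia surveys that
span seasons or climate zones, and at anyone validating
counterfactual-exposure adjustment pipelines against planted truth.

## Worked example

A fully synthetic run: 40 stations over a subtropical province, an
October-May survey of 8,000 adults in 21 districts, ground-truth curves
with cold-vs-warm contrasts of 0.10 mmol/L (NFG), 1.34 mmol/L (known
T2DM) and a U-shaped newly detected curve with vertex 19 °C.

```r
library(thermoglyc)

config <- run_config(
  truth   = truth_spec(seed = 11),
  weather = weather_field_spec(n_stations = 40, seasonal_mean = 19.5,
                               seasonal_amplitude = 12, seed = 11),
  n = 8000, n_districts = 21, cv_folds = 10, seed = 11)
art <- run_pipeline(config, "demo_run")

art$description$counts
#>         subgroup    n percent
#> 1            NFG 7232    90.4
#> 2          KNOWN  286     3.6
#> 3 NEWLY_DETECTED  482     6.0

subset(art$contrasts, select = c(subgroup, t_a, t_b, estimate, lo, hi))
#>                             subgroup  t_a  t_b estimate      lo    hi
#> total_lag0                     total  5.0 30.0    0.094  -0.094 0.282
#> NFG_lag0                         NFG  5.0 30.0    0.065  -0.065 0.194
#> KNOWN_lag0                     KNOWN  5.7 28.0    0.848   0.253 1.444
#> NEWLY_DETECTED_lag0.1 NEWLY_DETECTED  5.5 19.0    0.252  -0.052 0.557
#> NEWLY_DETECTED_lag0.2 NEWLY_DETECTED 29.2 19.0   -0.131  -0.416 0.154
```

Each row is the estimated FPG difference (mmol/L, with 95% CI) between a
cold and a warm temperature — e.g. known patients surveyed at ~5 °C carry
an FPG about 0.85 mmol/L above those surveyed at ~28 °C; the planted truth
1.34 lies inside the interval, and intervals for this 286-person subgroup
are wide at this sample size. Contrast endpoints are clamped to each
subgroup's observed exposure range.

```r
art$profile[, c("t_ref", "mean_fpg_known", "prevalence_pct",
                "control_rate_pct")]
#>   t_ref mean_fpg_known prevalence_pct control_rate_pct
#> 1   5.0           8.95           9.68             0.35
#> 2  10.0           8.50           9.61             3.15
#> 3  15.0           8.15           9.57             8.04
#> 4  20.0           8.03           9.55            10.84
#> 5  22.5           8.03           9.54            10.84
#> 6  25.0           8.05           9.54            10.14
#> 7  30.0           8.10           9.51             8.74
```

Adjusting everyone to a cold 5 °C raises known patients' mean FPG to
8.95 mmol/L and drops their glycemic control rate to 0.35%; at warm
references prevalence falls slightly as borderline undiagnosed
participants drop below the 7.0 mmol/L threshold. `demo_run/` also
contains per-subgroup curve tables, the AIC table, the interpolation CV
report (here R² = 0.95, RMSE = 1.49 °C for daily mean temperature), a
markdown report and a JSON manifest with checksums; reruns with the same
config and seed are bit-identical.

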