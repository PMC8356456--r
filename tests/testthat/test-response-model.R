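test_that("model spec validates basis dimension and duplicate terms", {
  expect_error(model_spec(k = 2), class = "thermoglyc_config_error")
  expect_error(model_spec(smooth_terms = c("age", "age")),
               class = "thermoglyc_config_error")
  sp <- model_spec(temp_metric = "tmin", lag = 3)
  expect_equal(thermoglyc:::temp_column(sp), "tmin_lag3")
})

test_that("a constant outcome is fitted as its intercept with zero residual SD", {
  co <- sim_model_cohort(200, list(NFG = function(t) 0 * t), seed = 1,
                         resid_sd = 0)
  co$fpg1 <- 5.5
  sp <- model_spec(smooth_terms = character(), linear_terms = character(),
                   random = NULL, subgroup = "NFG")
  fit <- fit_fpg_model(co, sp)
  expect_equal(unname(coef(fit$gam)[1]), 5.5, tolerance = 1e-6)
  expect_lt(fit$sigma, 1e-3)
})

test_that("fitted values plus residuals reproduce the outcome", {
  co <- sim_model_cohort(400, list(NFG = function(t) 5 - 0.01 * t), seed = 2)
  fit <- fit_fpg_model(co, model_spec(subgroup = "NFG",
                                      linear_terms = "sex"))
  y <- fit$gam$model$fpg1
  expect_equal(as.numeric(fitted(fit$gam) + residuals(fit$gam)), y,
               tolerance = 1e-8)
  # coefficient covariance is symmetric positive semidefinite, AIC finite
  V <- vcov(fit$gam)
  expect_equal(V, t(V), tolerance = 1e-10)
  expect_gte(min(eigen(V, symmetric = TRUE, only.values = TRUE)$values),
             -1e-8)
  expect_true(is.finite(fit$aic))
})

test_that("unpenalized spline fit equals ordinary least squares on its basis", {
  co <- sim_model_cohort(300, list(NFG = function(t) 5 + 0.002 * (30 - t)^2),
                         seed = 3)
  sp <- model_spec(smooth_terms = "age", linear_terms = "sex",
                   random = NULL, subgroup = "NFG", fx = TRUE)
  fit <- fit_fpg_model(co, sp)
  X <- predict(fit$gam, type = "lpmatrix")
  ols <- lm.fit(X, fit$gam$model$fpg1)
  expect_equal(unname(coef(fit$gam)), unname(ols$coefficients),
               tolerance = 1e-6)
})

test_that("smooth terms are centred so the intercept is interpretable", {
  co <- sim_model_cohort(500, list(NFG = function(t) 5 - 0.02 * t), seed = 4)
  fit <- fit_fpg_model(co, model_spec(subgroup = "NFG",
                                      linear_terms = "sex"))
  terms <- predict(fit$gam, type = "terms")
  # random-effect "smooths" carry no sum-to-zero constraint; check the
  # covariate smooths only
  smooth_cols <- setdiff(grep("^s\\(", colnames(terms)),
                         grep("district", colnames(terms)))
  for (j in smooth_cols) {
    expect_lt(abs(mean(terms[, j])), 1e-6)
  }
})

test_that("response curves are anchored at the minimum and shift-invariant", {
  co <- sim_model_cohort(2000, list(NFG = function(t) 5 + 0.001 * (30 - t)^2),
                         seed = 5, resid_sd = 0.3)
  sp <- model_spec(subgroup = "NFG", linear_terms = "sex")
  fit <- fit_fpg_model(co, sp)
  curve <- extract_response_curve(fit)
  anchor <- curve_anchor(curve)
  at_anchor <- curve[curve$temp == anchor, ]
  expect_equal(at_anchor$delta, 0, tolerance = 1e-12)
  expect_equal(at_anchor$hi - at_anchor$lo, 0, tolerance = 1e-12)
  expect_true(all(curve$lo <= curve$delta + 1e-12 &
                    curve$delta <= curve$hi + 1e-12))
  expect_true(all(curve$temp >= fit$temp_range[1] &
                    curve$temp <= fit$temp_range[2]))
  # adding a constant to the outcome moves only the intercept
  co2 <- co; co2$fpg1 <- co2$fpg1 + 5
  curve2 <- extract_response_curve(fit_fpg_model(co2, sp))
  expect_equal(curve2$delta, curve$delta, tolerance = 1e-6)
  expect_equal(curve_anchor(curve2), anchor)
})

test_that("contrasts behave at degenerate and out-of-range inputs", {
  co <- sim_model_cohort(800, list(NFG = function(t) 5 - 0.01 * t), seed = 6)
  fit <- fit_fpg_model(co, model_spec(subgroup = "NFG",
                                      linear_terms = "sex"))
  same <- estimate_contrast(fit, 20, 20)
  expect_identical(same$estimate, 0)
  expect_identical(same$hi - same$lo, 0)
  expect_error(estimate_contrast(fit, 2, 20),
               class = "thermoglyc_range_error")
  # increasing truth: contrast(low, high) is negative
  co_up <- sim_model_cohort(2000, list(NFG = function(t) 5 + 0.05 * t),
                            seed = 7, resid_sd = 0.3)
  fit_up <- fit_fpg_model(co_up, model_spec(subgroup = "NFG",
                                            linear_terms = "sex"))
  expect_lt(estimate_contrast(fit_up, 7, 28)$estimate, 0)
})

test_that("analytic contrast CIs agree with coefficient-resampling CIs", {
  co <- sim_model_cohort(2000, list(NFG = function(t) 5 - 0.02 * t), seed = 8)
  fit <- fit_fpg_model(co, model_spec(subgroup = "NFG",
                                      linear_terms = "sex"))
  an <- estimate_contrast(fit, 7, 28)
  sim <- contrast_ci_sim(fit, 7, 28, nsim = 10000, seed = 8)
  width_an <- an$hi - an$lo
  width_sim <- sim$hi - sim$lo
  expect_equal(width_sim, width_an, tolerance = 0.05 * width_an)
  expect_equal(sim$estimate, an$estimate, tolerance = 1e-9)
})

test_that("with zero true effects contrasts cover zero and sigma is recovered", {
  co <- sim_model_cohort(5000, list(NFG = function(t) 5 + 0 * t), seed = 9,
                         resid_sd = 0.8)
  co$age <- co$age * 0 + 50; co$bmi <- co$bmi * 0 + 23
  co$sex <- "male"  # kill covariate effects so sigma_true = 0.8 exactly
  fit <- fit_fpg_model(co, model_spec(subgroup = "NFG",
                                      smooth_terms = character(),
                                      linear_terms = character()))
  ctr <- estimate_contrast(fit, 7, 28)
  expect_true(ctr$lo <= 0 && 0 <= ctr$hi)
  # district intercepts are absorbed by the random effect, so the residual
  # SD estimates the planted 0.8 mmol/L
  expect_equal(fit$sigma, 0.8, tolerance = 0.05)
})

test_that("AIC selection recovers the generating exposure metric", {
  set.seed(10)
  wins <- 0L
  for (rep in 1:5) {
    co <- sim_model_cohort(2500, list(NFG = function(t) 6 - 0.05 * t),
                           seed = 100 + rep, resid_sd = 0.5)
    co$tmin_lag0 <- co$tmean_lag0 - 4 + rnorm(nrow(co), 0, 2)
    co$tmax_lag0 <- co$tmean_lag0 + 4 + rnorm(nrow(co), 0, 2)
    sel <- select_exposure_metric(co, metrics = c("tmean", "tmin", "tmax"),
                                  lags = 0, subgroup = "NFG",
                                  smooth_terms = "age",
                                  linear_terms = "sex")
    wins <- wins + (sel$spec$temp_metric == "tmean")
    expect_equal(nrow(sel$aic_table), 3)
    expect_equal(length(unique(sel$aic_table$n)), 1)
  }
  expect_gte(wins, 4L)
})

test_that("metric selection handles single candidates and ties", {
  co <- sim_model_cohort(600, list(NFG = function(t) 6 - 0.05 * t),
                         seed = 11)
  one <- select_exposure_metric(co, metrics = "tmean", lags = 0,
                                subgroup = "NFG", smooth_terms = "age",
                                linear_terms = "sex")
  expect_equal(one$spec$temp_metric, "tmean")
  # byte-identical candidates tie; first declared candidate kept
  co$tmin_lag0 <- co$tmean_lag0
  expect_message(
    tie <- select_exposure_metric(co, metrics = c("tmean", "tmin"),
                                  lags = 0, subgroup = "NFG",
                                  smooth_terms = "age",
                                  linear_terms = "sex"),
    "tie")
  expect_equal(tie$spec$temp_metric, "tmean")
})

test_that("basis-dimension selection is AIC-driven and handles a singleton grid", {
  co <- sim_model_cohort(3000, list(NFG = function(t) 5 + 0.002 * (t - 18)^2),
                         seed = 12, resid_sd = 0.5)
  sp <- model_spec(subgroup = "NFG", smooth_terms = "age",
                   linear_terms = "sex")
  single <- select_basis_dimension(co, sp, k_grid = 3)
  expect_equal(single$k, 3)
  sel <- select_basis_dimension(co, sp, k_grid = c(3, 4, 5))
  # quadratic truth: k = 3 stays within 2 AIC units of the grid optimum
  expect_lte(sel$aic_table$aic[1], min(sel$aic_table$aic) + 2)
})

test_that("interaction test requires at least two subgroups", {
  co <- sim_model_cohort(300, list(NFG = function(t) 5 - 0.01 * t), seed = 13)
  expect_error(test_interaction(co), class = "thermoglyc_config_error")
})

test_that("strong subgroup slope differences are detected", {
  co <- sim_model_cohort(
    6000, list(NFG = function(t) 5 - 0.004 * (t - 30),
               KNOWN = function(t) 8 - 0.08 * (t - 30)),
    seed = 14, resid_sd = 0.8, mix = c(0.9, 0.1))
  res <- test_interaction(co)
  expect_lt(res$p_value, 0.001)
  expect_lt(res$aic_interaction, res$aic_shared)
})

test_that("constant covariates are dropped with a notice", {
  co <- sim_model_cohort(500, list(KNOWN = function(t) 8 - 0.05 * t),
                         seed = 15)
  co$hypoglycemic_med <- FALSE
  sp <- model_spec(subgroup = "KNOWN", smooth_terms = "age",
                   linear_terms = c("sex", "hypoglycemic_med"))
  expect_message(fit <- fit_fpg_model(co, sp), "hypoglycemic_med")
  expect_false("hypoglycemic_medTRUE" %in% names(coef(fit$gam)))
})
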