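# Temperature-response model: Gaussian additive mixed model for FPG with
# penalized cubic-regression splines for daily mean temperature, humidity,
# age and BMI, categorical fixed effects, and a district random intercept
# (fitted with mgcv; the random intercept is the usual ridge-penalized
# district factor, s(district, bs = "re"), with its variance chosen by
# REML). Curves are reported as differences from the minimum-FPG
# temperature; contrasts carry analytic Gaussian CIs from the coefficient
# covariance.

#' Specify an FPG additive model
#'
#' @param temp_metric temperature exposure metric: `"tmean"`, `"tmin"` or
#'   `"tmax"`.
#' @param lag exposure lag in days (0-6); the model term is the column
#'   `<metric>_lag<lag>`.
#' @param k basis dimension of the penalized cubic regression spline for
#'   temperature (>= 3; default 3).
#' @param smooth_terms further columns modelled with cubic splines (default
#'   humidity at lag 0, age, BMI; each at `k = 3`).
#' @param linear_terms categorical/linear fixed-effect columns.
#' @param extra_terms optional additional linear columns (e.g. sunlight and
#'   precipitation for the extended covariate model).
#' @param random grouping column for the random intercept (`NULL` to omit).
#' @param subgroup which participants enter the fit: `"total"` or one of
#'   `"NFG"`, `"KNOWN"`, `"NEWLY_DETECTED"`.
#' @param outcome outcome column (FPG, mmol/L).
#' @param fx if `TRUE`, fit unpenalized regression splines (fixed degrees
#'   of freedom) instead of penalized ones.
#' @return object of class `fpg_model_spec`.
#' @export
model_spec <- function(temp_metric = c("tmean", "tmin", "tmax"), lag = 0,
                       k = 3,
                       smooth_terms = c("humidity_lag0", "age", "bmi"),
                       linear_terms = c("sex", "education", "career",
                                        "physical_activity",
                                        "sedentary_time", "smoking",
                                        "drinking", "hypoglycemic_med"),
                       extra_terms = NULL,
                       random = "district_id",
                       subgroup = "total",
                       outcome = "fpg1",
                       fx = FALSE) {
  temp_metric <- match.arg(temp_metric)
  if (k < 3) stop_thermoglyc("k must be >= 3", "thermoglyc_config_error")
  stopifnot(lag >= 0, is_flag(fx))
  terms <- c(outcome, smooth_terms, linear_terms, extra_terms, random)
  if (anyDuplicated(terms)) {
    stop_thermoglyc("duplicated model terms", "thermoglyc_config_error")
  }
  structure(
    list(temp_metric = temp_metric, lag = as.integer(lag), k = as.integer(k),
         smooth_terms = smooth_terms, linear_terms = linear_terms,
         extra_terms = extra_terms, random = random, subgroup = subgroup,
         outcome = outcome, fx = fx),
    class = "fpg_model_spec"
  )
}

temp_column <- function(spec) paste0(spec$temp_metric, "_lag", spec$lag)

# rows of `cohort` entering a fit under `spec` (subgroup + complete cases)
.model_rows <- function(cohort, spec, extra_cols = NULL) {
  stopifnot("subgroup" %in% names(cohort) || spec$subgroup == "total")
  sel <- if (spec$subgroup == "total") rep(TRUE, nrow(cohort)) else {
    !is.na(cohort$subgroup) & cohort$subgroup == spec$subgroup
  }
  cols <- unique(c(spec$outcome, temp_column(spec), spec$smooth_terms,
                   spec$linear_terms, spec$extra_terms, spec$random,
                   extra_cols))
  missing_cols <- setdiff(cols, names(cohort))
  if (length(missing_cols)) {
    stop_thermoglyc(paste("missing model columns:",
                          paste(missing_cols, collapse = ", ")),
                    "thermoglyc_config_error")
  }
  sel & complete.cases(cohort[cols])
}

.build_formula <- function(spec, data) {
  k3 <- 3L
  tcol <- temp_column(spec)
  fx_part <- if (spec$fx) ", fx=TRUE" else ""
  rhs <- sprintf('s(%s, k=%d, bs="cr"%s)', tcol, spec$k, fx_part)
  dropped <- character()
  for (v in spec$smooth_terms) {
    if (length(unique(data[[v]])) < spec$k + 1) {
      dropped <- c(dropped, v); next
    }
    rhs <- c(rhs, sprintf('s(%s, k=%d, bs="cr"%s)', v, k3, fx_part))
  }
  for (v in c(spec$linear_terms, spec$extra_terms)) {
    if (length(unique(data[[v]])) < 2) { dropped <- c(dropped, v); next }
    rhs <- c(rhs, v)
  }
  if (!is.null(spec$random)) {
    rhs <- c(rhs, sprintf('s(%s, bs="re")', spec$random))
  }
  list(formula = as.formula(paste(spec$outcome, "~",
                                  paste(rhs, collapse = " + "))),
       dropped = dropped)
}

#' Fit the FPG temperature-response model
#'
#' Fits the Gaussian additive model for the requested subgroup: penalized
#' cubic regression splines for temperature (basis dimension `spec$k`),
#' humidity, age and BMI (k = 3), the categorical covariates as fixed
#' effects, and a district random intercept, by REML. Covariates that are
#' constant within the subgroup (e.g. hypoglycemic-medicine use among NFG
#' participants) are dropped with a notice; rows with missing model
#' variables are excluded (complete-case analysis) and counted.
#'
#' @param cohort classified cohort with exposures attached.
#' @param spec a [model_spec()].
#' @return object of class `fpg_fit`: list with the `mgcv::gam` fit
#'   (`$gam`), `$spec`, `$n_obs`, `$n_dropped_rows`, `$dropped_terms`,
#'   `$aic` and `$temp_range` (observed exposure range).
#' @export
fit_fpg_model <- function(cohort, spec) {
  stopifnot(inherits(spec, "fpg_model_spec"))
  rows <- .model_rows(cohort, spec)
  data <- cohort[rows, , drop = FALSE]
  if (nrow(data) == 0) {
    stop_thermoglyc("no observations for subgroup", "thermoglyc_fit_error")
  }
  for (v in c(spec$linear_terms, spec$extra_terms)) {
    if (is.character(data[[v]]) || is.logical(data[[v]])) {
      data[[v]] <- factor(data[[v]])
    }
  }
  if (!is.null(spec$random)) data[[spec$random]] <- factor(data[[spec$random]])
  bf <- .build_formula(spec, data)
  if (length(bf$dropped)) {
    message("dropping constant term(s): ", paste(bf$dropped, collapse = ", "))
  }
  fit <- tryCatch(
    mgcv::gam(bf$formula, data = data, method = "REML"),
    error = function(e) {
      # REML cannot handle degenerate (e.g. zero-variance) responses;
      # fall back to the prediction-error criterion before giving up
      tryCatch(
        mgcv::gam(bf$formula, data = data, method = "GCV.Cp"),
        error = function(e2) {
          stop_thermoglyc(paste("model fit failed:", conditionMessage(e2)),
                          "thermoglyc_fit_error")
        })
    })
  tcol <- temp_column(spec)
  in_subgroup <- if (spec$subgroup == "total") rep(TRUE, nrow(cohort)) else {
    !is.na(cohort$subgroup) & cohort$subgroup == spec$subgroup
  }
  structure(
    list(gam = fit, spec = spec, n_obs = nrow(data),
         n_dropped_rows = sum(in_subgroup & !rows),
         dropped_terms = bf$dropped, aic = AIC(fit),
         temp_range = range(data[[tcol]]),
         sigma = sqrt(fit$sig2)),
    class = "fpg_fit"
  )
}

#' @export
print.fpg_fit <- function(x, ...) {
  cat(sprintf("FPG additive model fit [%s], exposure %s, k=%d\n",
              x$spec$subgroup, temp_column(x$spec), x$spec$k))
  cat(sprintf("  n = %d (dropped %d incomplete), AIC = %.1f, residual SD = %.3f\n",
              x$n_obs, x$n_dropped_rows, x$aic, x$sigma))
  invisible(x)
}

# reference row for curve/contrast prediction: medians for numerics, first
# observed level for factors. Non-temperature columns cancel in every
# difference contrast, so their values are arbitrary.
.reference_row <- function(fit) {
  mf <- fit$gam$model
  ref <- lapply(mf, function(col) {
    if (is.factor(col)) factor(levels(col)[1], levels = levels(col))
    else median(col)
  })
  as.data.frame(ref, stringsAsFactors = FALSE)[1, , drop = FALSE]
}

.lpmatrix_at <- function(fit, temps) {
  ref <- .reference_row(fit)
  nd <- ref[rep(1, length(temps)), , drop = FALSE]
  nd[[temp_column(fit$spec)]] <- temps
  predict(fit$gam, newdata = nd, type = "lpmatrix")
}

#' Extract the anchored temperature-FPG response curve
#'
#' Evaluates the fitted temperature smooth on a regular grid over the
#' observed exposure range, locates the minimum-FPG temperature `t*` (ties
#' broken toward the warmer temperature), and re-expresses the curve as the
#' difference in FPG relative to `t*` with pointwise 95% CIs from the
#' linear-contrast variance \eqn{c^T \Sigma c} (coefficient covariance
#' \eqn{\Sigma} from the fit). By construction `delta_fpg(t*) = 0` with a
#' zero-width interval.
#'
#' @param fit an [fit_fpg_model()] result.
#' @param grid_step grid resolution, degrees C (default 0.1).
#' @return object of class `fpg_curve`: data.frame with `temp`, `delta`,
#'   `lo`, `hi`; attributes `anchor` (t*, degrees C), `subgroup`, `lag`.
#' @export
extract_response_curve <- function(fit, grid_step = 0.1) {
  stopifnot(inherits(fit, "fpg_fit"))
  rng <- fit$temp_range
  grid <- seq(rng[1], rng[2], by = grid_step)
  if (grid[length(grid)] < rng[2]) grid <- c(grid, rng[2])
  Xp <- .lpmatrix_at(fit, grid)
  sval <- drop(Xp %*% coef(fit$gam))
  anchor_idx <- max(which(sval <= min(sval) + 1e-12))  # ties -> warmer
  D <- sweep(Xp, 2, Xp[anchor_idx, ])
  Vp <- vcov(fit$gam)
  se <- sqrt(pmax(0, rowSums((D %*% Vp) * D)))
  delta <- sval - sval[anchor_idx]
  structure(
    data.frame(temp = grid, delta = delta,
               lo = delta - 1.96 * se, hi = delta + 1.96 * se),
    anchor = grid[anchor_idx],
    subgroup = fit$spec$subgroup, lag = fit$spec$lag,
    class = c("fpg_curve", "data.frame")
  )
}

#' Anchor (minimum-FPG) temperature of a curve
#' @param curve an `fpg_curve`.
#' @return degrees C.
#' @export
curve_anchor <- function(curve) attr(curve, "anchor")

#' Estimate an FPG difference between two temperatures
#'
#' Point estimate `smooth(t_a) - smooth(t_b)` with analytic 95% CI
#' `estimate +/- 1.96 sqrt(c' Sigma c)`, `c` the difference of the two
#' basis rows. The degenerate contrast `(t, t)` is exactly 0 with a
#' zero-width interval.
#'
#' @param fit an [fit_fpg_model()] result.
#' @param t_a,t_b temperatures within the observed exposure range, degrees C.
#' @return data.frame with `t_a`, `t_b`, `estimate`, `lo`, `hi`, `se`,
#'   `subgroup`, `lag` (mmol/L).
#' @export
estimate_contrast <- function(fit, t_a, t_b) {
  stopifnot(inherits(fit, "fpg_fit"))
  rng <- fit$temp_range
  if (t_a < rng[1] - 1e-9 || t_a > rng[2] + 1e-9 ||
      t_b < rng[1] - 1e-9 || t_b > rng[2] + 1e-9) {
    stop_thermoglyc(
      sprintf("contrast temperatures outside observed range [%.1f, %.1f]",
              rng[1], rng[2]), "thermoglyc_range_error")
  }
  Xp <- .lpmatrix_at(fit, c(t_a, t_b))
  d <- Xp[1, ] - Xp[2, ]
  est <- sum(d * coef(fit$gam))
  se <- sqrt(max(0, drop(d %*% vcov(fit$gam) %*% d)))
  data.frame(t_a = t_a, t_b = t_b, estimate = est,
             lo = est - 1.96 * se, hi = est + 1.96 * se, se = se,
             subgroup = fit$spec$subgroup, lag = fit$spec$lag)
}

#' Simulation cross-check of a contrast CI
#'
#' Resamples model coefficients from their Gaussian posterior
#' (`N(beta, Sigma)`) and reports percentile bounds of the contrast, as an
#' independent check on the analytic interval of [estimate_contrast()].
#'
#' @inheritParams estimate_contrast
#' @param nsim number of coefficient draws.
#' @param seed RNG seed.
#' @return data.frame with `estimate`, `lo`, `hi`.
#' @export
contrast_ci_sim <- function(fit, t_a, t_b, nsim = 10000, seed = 1L) {
  Xp <- .lpmatrix_at(fit, c(t_a, t_b))
  d <- Xp[1, ] - Xp[2, ]
  beta <- coef(fit$gam); Vp <- vcov(fit$gam)
  draws <- with_stream(seed, 51L, mgcv::rmvn(nsim, beta, Vp))
  vals <- drop(draws %*% d)
  q <- quantile(vals, c(0.025, 0.975), names = FALSE)
  data.frame(estimate = sum(d * beta), lo = q[1], hi = q[2])
}

#' Select the exposure metric (and lag) by AIC
#'
#' Fits one model per candidate temperature metric/lag on an identical set
#' of rows (complete cases across all candidate exposure columns) and
#' returns the specification with minimum AIC. Ties are broken by declared
#' candidate order, with a message.
#'
#' @param cohort classified cohort with exposures.
#' @param metrics candidate metrics.
#' @param lags candidate lags.
#' @param ... further arguments to [model_spec()] shared by all candidates.
#' @return list with `spec` (winning [model_spec()]), `aic_table`
#'   (data.frame of metric, lag, aic, n), and `fits` (named list).
#' @export
select_exposure_metric <- function(cohort,
                                   metrics = c("tmean", "tmin", "tmax"),
                                   lags = 0, ...) {
  cand <- expand.grid(metric = metrics, lag = lags,
                      stringsAsFactors = FALSE)
  if (nrow(cand) < 1) {
    stop_thermoglyc("need at least one candidate", "thermoglyc_config_error")
  }
  specs <- lapply(seq_len(nrow(cand)), function(i) {
    model_spec(temp_metric = cand$metric[i], lag = cand$lag[i], ...)
  })
  # identical observation sets: complete cases over every candidate column
  all_cols <- unique(vapply(specs, temp_column, character(1)))
  rows <- .model_rows(cohort, specs[[1]], extra_cols = all_cols)
  data <- cohort[rows, , drop = FALSE]
  fits <- lapply(specs, function(sp) fit_fpg_model(data, sp))
  aic <- vapply(fits, function(f) f$aic, numeric(1))
  n <- vapply(fits, function(f) f$n_obs, numeric(1))
  if (length(unique(n)) != 1) {
    stop_thermoglyc("candidates fitted on differing rows",
                    "thermoglyc_comparison_error")
  }
  best <- which.min(aic)  # which.min takes the first minimum: declared order
  if (sum(abs(aic - aic[best]) < 1e-9) > 1) {
    message("AIC tie: keeping first candidate in declared order")
  }
  tab <- data.frame(metric = cand$metric, lag = cand$lag, aic = aic, n = n)
  names(fits) <- paste0(cand$metric, "_lag", cand$lag)
  list(spec = specs[[best]], aic_table = tab, fits = fits)
}

#' Select the temperature basis dimension by AIC
#'
#' Refits `spec` at each candidate basis dimension and returns the AIC
#' minimizer (the graphical-smoothness criterion sometimes used alongside
#' AIC is replaced by this objective rule).
#'
#' @param cohort classified cohort.
#' @param spec base [model_spec()].
#' @param k_grid candidate basis dimensions.
#' @return list with `k` (chosen), `aic_table`.
#' @export
select_basis_dimension <- function(cohort, spec, k_grid = c(3, 4, 5)) {
  if (length(k_grid) < 1) {
    stop_thermoglyc("k_grid must be nonempty", "thermoglyc_config_error")
  }
  aic <- vapply(k_grid, function(k) {
    sp <- spec; sp$k <- as.integer(k)
    fit_fpg_model(cohort, sp)$aic
  }, numeric(1))
  list(k = k_grid[which.min(aic)],
       aic_table = data.frame(k = k_grid, aic = aic))
}

#' Test whether the temperature-FPG curve differs by diabetes status
#'
#' Compares a total-population model with a single shared temperature
#' smooth (plus subgroup main effects) against one that adds
#' subgroup-specific difference smooths of temperature (an ordered-factor
#' by-variable smooth), i.e. a temperature-by-status interaction. With the
#' default `fx = TRUE` the spline bases have fixed degrees of freedom and
#' the nested-model F test is exact under the Gaussian model; with
#' `fx = FALSE` both models are penalized fits compared by an approximate
#' likelihood-ratio test.
#'
#' @param cohort classified cohort spanning at least two subgroups.
#' @param temp exposure column (default `tmean_lag0`).
#' @param k temperature basis dimension.
#' @param smooth_terms,linear_terms,random as in [model_spec()]; defaults
#'   are lighter than the main model since the test targets only the
#'   temperature-by-status term.
#' @param fx use fixed-df regression splines (exact F test).
#' @return list with `p_value`, `statistic`, `df`, `aic_shared`,
#'   `aic_interaction`.
#' @export
test_interaction <- function(cohort, temp = "tmean_lag0", k = 3,
                             smooth_terms = c("age", "bmi"),
                             linear_terms = c("sex"),
                             random = "district_id", fx = TRUE) {
  stopifnot("subgroup" %in% names(cohort))
  sub <- droplevels(factor(cohort$subgroup))
  if (nlevels(sub) < 2) {
    stop_thermoglyc("interaction test needs >= 2 subgroups",
                    "thermoglyc_config_error")
  }
  cols <- c("fpg1", temp, smooth_terms, linear_terms, random)
  keep <- complete.cases(cohort[cols]) & !is.na(sub)
  data <- cohort[keep, , drop = FALSE]
  data$..sub <- droplevels(sub[keep])
  data$..osub <- as.ordered(data$..sub)
  if (!is.null(random)) data[[random]] <- factor(data[[random]])
  for (v in linear_terms) {
    if (is.character(data[[v]]) || is.logical(data[[v]])) {
      data[[v]] <- factor(data[[v]])
    }
  }
  fx_part <- if (fx) ", fx=TRUE" else ""
  base_terms <- c(
    sprintf('s(%s, k=%d, bs="cr"%s)', temp, k, fx_part),
    "..sub",
    sprintf('s(%s, k=3, bs="cr"%s)', smooth_terms, fx_part),
    linear_terms,
    if (!is.null(random)) sprintf('s(%s, bs="re")', random)
  )
  f0 <- as.formula(paste("fpg1 ~", paste(base_terms, collapse = " + ")))
  f1 <- as.formula(paste(
    "fpg1 ~", paste(c(base_terms,
                      sprintf('s(%s, by=..osub, k=%d, bs="cr"%s)',
                              temp, k, fx_part)), collapse = " + ")))
  method <- if (fx) "REML" else "ML"
  m0 <- mgcv::gam(f0, data = data, method = method)
  m1 <- mgcv::gam(f1, data = data, method = method)
  cmp <- anova(m0, m1, test = if (fx) "F" else "Chisq")
  p <- cmp[2, ncol(cmp)]
  list(p_value = p,
       statistic = if (fx) cmp$F[2] else cmp$Deviance[2],
       df = cmp$Df[2],
       aic_shared = AIC(m0), aic_interaction = AIC(m1))
}
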