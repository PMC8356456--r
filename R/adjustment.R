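# Counterfactual temperature adjustment: shift each participant's FPG from
# their survey-day temperature to a reference temperature along their
# subgroup's fitted response curve, then recompute T2DM prevalence
# (cases / total) and glycemic control rate (controlled known patients /
# known patients) at each reference temperature.

#' Evaluate a response curve at arbitrary temperatures
#'
#' Linear interpolation between the curve's grid points; temperatures
#' outside the grid are clamped to its range.
#'
#' @param curve an `fpg_curve` (or any data.frame with `temp`, `delta`).
#' @param t temperatures, degrees C.
#' @return curve values, mmol/L.
#' @export
curve_value <- function(curve, t) {
  rng <- range(curve$temp)
  t <- pmin(rng[2], pmax(rng[1], t))
  approx(curve$temp, curve$delta, xout = t, ties = "ordered")$y
}

#' FPG difference between observed and reference temperature
#'
#' `curve(t_obs) - curve(t_ref)`: the portion of a participant's FPG
#' attributed to being surveyed at `t_obs` rather than at the reference
#' temperature, read off the subgroup's anchored response curve.
#'
#' @param curve subgroup response curve ([extract_response_curve()]).
#' @param t_obs survey-day temperature(s), degrees C.
#' @param t_ref reference temperature(s), degrees C (recycled).
#' @return mmol/L.
#' @export
delta_fpg <- function(curve, t_obs, t_ref) {
  curve_value(curve, t_obs) - curve_value(curve, t_ref)
}

#' Temperature-adjusted FPG
#'
#' `fpg1 - delta`. Adjusted values below zero are physiologically
#' implausible; they are floored at zero and counted in
#' `attr(, "n_floored")`.
#'
#' @param fpg1 observed FPG, mmol/L (> 0).
#' @param delta FPG difference from [delta_fpg()], mmol/L.
#' @return adjusted FPG, mmol/L.
#' @export
adjust_fpg <- function(fpg1, delta) {
  out <- fpg1 - delta
  n_floored <- sum(out < 0)
  if (n_floored > 0) {
    warning(sprintf("%d adjusted FPG value(s) below 0 floored", n_floored),
            call. = FALSE)
    out <- pmax(out, 0)
  }
  attr(out, "n_floored") <- n_floored
  out
}

# per-participant adjusted FPG using each subgroup's own curve
.adjusted_fpg_vector <- function(cohort, curves, t_ref, exposure) {
  stopifnot("subgroup" %in% names(cohort), exposure %in% names(cohort))
  groups <- unique(as.character(cohort$subgroup))
  missing_curves <- setdiff(groups, names(curves))
  if (length(missing_curves)) {
    stop_thermoglyc(paste("no response curve for subgroup(s):",
                          paste(missing_curves, collapse = ", ")),
                    "thermoglyc_config_error")
  }
  t_ref <- rep_len(t_ref, nrow(cohort))
  adj <- numeric(nrow(cohort))
  for (g in groups) {
    i <- cohort$subgroup == g
    d <- delta_fpg(curves[[g]], cohort[[exposure]][i], t_ref[i])
    adj[i] <- suppressWarnings(adjust_fpg(cohort$fpg1[i], d))
  }
  adj
}

#' Temperature-adjusted T2DM prevalence
#'
#' Adjusts every participant's FPG to the reference temperature along their
#' own subgroup's response curve and recomputes prevalence. Known patients
#' always count as cases. Under the default `rule = "reclassify"` all
#' undiagnosed participants (NFG and newly detected alike) are re-evaluated
#' against the 7.0 mmol/L threshold on their adjusted FPG, so prevalence at
#' a warm reference can drop below the crude rate. `rule = "literal"`
#' instead keeps every originally newly detected participant as a case and
#' re-evaluates only the NFG subgroup (the strict reading of the
#' case-count definition); the two rules agree when no adjusted FPG crosses
#' the threshold.
#'
#' @param cohort classified cohort with exposures.
#' @param curves named list of `fpg_curve`s, one per populated subgroup.
#' @param t_ref reference temperature, degrees C (scalar, or one value per
#'   participant e.g. to adjust everyone to their own survey temperature).
#' @param exposure exposure column (default `tmean_lag0`).
#' @param rule `"reclassify"` (default) or `"literal"`, see Details.
#' @return object of class `fpg_adjustment`: list with `t_ref`,
#'   `prevalence`, counts `n1`, `n3`, `mean_adjusted_fpg` (per subgroup and
#'   total) and the `adjusted_fpg` vector.
#' @export
adjusted_prevalence <- function(cohort, curves, t_ref,
                                exposure = "tmean_lag0",
                                rule = c("reclassify", "literal")) {
  rule <- match.arg(rule)
  adj <- .adjusted_fpg_vector(cohort, curves, t_ref, exposure)
  known <- cohort$subgroup == "KNOWN"
  case <- if (rule == "reclassify") {
    known | (!known & adj >= 7.0)
  } else {
    known | cohort$subgroup == "NEWLY_DETECTED" |
      (cohort$subgroup == "NFG" & adj >= 7.0)
  }
  n1 <- sum(case); n3 <- nrow(cohort)
  means <- c(tapply(adj, cohort$subgroup, mean), Total = mean(adj))
  structure(
    list(t_ref = if (length(unique(t_ref)) == 1) t_ref[1] else NA_real_,
         rule = rule, prevalence = n1 / n3, n1 = n1, n3 = n3,
         mean_adjusted_fpg = means, adjusted_fpg = adj),
    class = "fpg_adjustment")
}

#' Temperature-adjusted glycemic control rate
#'
#' Proportion of known T2DM patients whose temperature-adjusted FPG is
#' below 7.0 mmol/L.
#'
#' @inheritParams adjusted_prevalence
#' @param curve_known the known-T2DM response curve (defaults to
#'   `curves[["KNOWN"]]` when `curves` given instead).
#' @return object of class `fpg_adjustment`: list with `t_ref`,
#'   `control_rate`, counts `n2`, `n4`, and the known patients'
#'   `adjusted_fpg`.
#' @export
adjusted_control_rate <- function(cohort, curve_known, t_ref,
                                  exposure = "tmean_lag0") {
  known <- cohort[!is.na(cohort$subgroup) & cohort$subgroup == "KNOWN", ,
                  drop = FALSE]
  if (nrow(known) == 0) {
    stop_thermoglyc("control rate undefined: no known T2DM patients",
                    "thermoglyc_undefined_rate")
  }
  t_ref <- rep_len(t_ref, nrow(known))
  d <- delta_fpg(curve_known, known[[exposure]], t_ref)
  adj <- suppressWarnings(adjust_fpg(known$fpg1, d))
  n2 <- sum(adj < 7.0); n4 <- nrow(known)
  structure(
    list(t_ref = if (length(unique(t_ref)) == 1) t_ref[1] else NA_real_,
         control_rate = n2 / n4, n2 = n2, n4 = n4, adjusted_fpg = adj),
    class = "fpg_adjustment")
}

#' Adjustment profile over a set of reference temperatures
#'
#' Runs [adjusted_prevalence()] and [adjusted_control_rate()] at each
#' reference temperature and tabulates mean adjusted FPG per subgroup,
#' prevalence and control rate (percent).
#'
#' @inheritParams adjusted_prevalence
#' @param refs reference temperatures, degrees C (default
#'   `c(5, 10, 15, 20, 22.5, 25, 30)`).
#' @return data.frame with one row per reference temperature: `t_ref`,
#'   `mean_fpg_*` per subgroup and total, `prevalence_pct`,
#'   `control_rate_pct`, and the component counts `n1`-`n4`.
#' @export
adjustment_profile <- function(cohort, curves,
                               refs = c(5, 10, 15, 20, 22.5, 25, 30),
                               exposure = "tmean_lag0",
                               rule = "reclassify") {
  rows <- lapply(refs, function(tr) {
    prev <- adjusted_prevalence(cohort, curves, tr, exposure, rule)
    ctrl <- adjusted_control_rate(cohort, curves[["KNOWN"]], tr, exposure)
    m <- prev$mean_adjusted_fpg
    data.frame(
      t_ref = tr,
      mean_fpg_nfg = unname(m["NFG"]),
      mean_fpg_known = unname(m["KNOWN"]),
      mean_fpg_new = unname(m["NEWLY_DETECTED"]),
      mean_fpg_total = unname(m["Total"]),
      prevalence_pct = 100 * prev$prevalence,
      control_rate_pct = 100 * ctrl$control_rate,
      n1 = prev$n1, n2 = ctrl$n2, n3 = prev$n3, n4 = ctrl$n4)
  })
  do.call(rbind, rows)
}
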