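test_that("delta_fpg reads differences off the curve with clamping", {
  lin <- toy_curve(function(t) 0.01 * (30 - t))
  expect_equal(delta_fpg(lin, 20, 20), 0)
  expect_equal(delta_fpg(lin, 20, 30), 0.10, tolerance = 1e-12)
  # out-of-range temperatures clamp to the curve range
  expect_equal(delta_fpg(lin, 2, 30), delta_fpg(lin, 5, 30))
  expect_equal(delta_fpg(lin, 35, 30), 0)
  # parabola with curve(5) - curve(30) = 1.34, anchored at 30
  known <- toy_curve(function(t) 1.34 / 625 * (30 - t)^2)
  expect_equal(delta_fpg(known, 5, 30), 1.34, tolerance = 1e-9)
})

test_that("adjust_fpg applies the shift and floors implausible values", {
  expect_equal(as.numeric(adjust_fpg(9.0, 1.34)), 7.66)
  expect_equal(as.numeric(adjust_fpg(6.5, 0.0)), 6.5)
  # negative delta: adjusting toward a colder reference raises FPG
  expect_equal(as.numeric(adjust_fpg(5.0, -0.5)), 5.5)
  expect_warning(out <- adjust_fpg(1.0, 2.5), "floored")
  expect_equal(as.numeric(out), 0)
  expect_equal(attr(out, "n_floored"), 1)
})

test_that("hand-worked toy cohort reproduces the reclassification arithmetic", {
  # 1 KNOWN; 1 NEWLY at 7.2 whose delta +0.3 adjusts to 6.9 (drops out);
  # 1 NFG at 6.9 whose delta -0.2 adjusts to 7.1 (becomes a case);
  # 7 NFG far below threshold -> N1 = 2, prevalence 0.20
  co <- toy_cohort(
    fpg = c(8.0, 7.2, 6.9, rep(5.0, 7)),
    subgroup = c("KNOWN", "NEWLY_DETECTED", "NFG", rep("NFG", 7)),
    t_obs = c(20, 10, 28, rep(20, 7)))
  curves <- list(
    KNOWN = flat_curve(),
    # delta(10, 20) = +0.3 for the newly detected curve
    NEWLY_DETECTED = toy_curve(function(t) 0.03 * (20 - t), from = 5),
    # delta(28, 20) = -0.2 for the NFG curve
    NFG = toy_curve(function(t) 0.025 * (20 - t), from = 5))
  res <- adjusted_prevalence(co, curves, t_ref = 20)
  expect_equal(res$n1, 2)
  expect_equal(res$prevalence, 0.20)
  # literal rule keeps the original newly detected participant as a case
  lit <- adjusted_prevalence(co, curves, t_ref = 20, rule = "literal")
  expect_equal(lit$n1, 3)
})

test_that("zero adjustment reproduces the crude prevalence from survey counts", {
  n_nfg <- 23877; n_known <- 916; n_new <- 1557
  co <- toy_cohort(
    fpg = c(rep(5.5, n_nfg), rep(8.5, n_known), rep(7.5, n_new)),
    subgroup = c(rep("NFG", n_nfg), rep("KNOWN", n_known),
                 rep("NEWLY_DETECTED", n_new)),
    t_obs = 20)
  curves <- list(NFG = flat_curve(), KNOWN = flat_curve(),
                 NEWLY_DETECTED = flat_curve())
  res <- adjusted_prevalence(co, curves, t_ref = 15)
  expect_equal(res$n1, n_known + n_new)
  expect_equal(res$prevalence, (916 + 1557) / 26350, tolerance = 1e-12)
  # prevalence never drops below the known-patient share
  expect_gte(res$prevalence, n_known / nrow(co))
})

test_that("control rate counts known patients below threshold", {
  co <- toy_cohort(c(6.5, 7.2, 6.9), rep("KNOWN", 3), t_obs = 20)
  res <- adjusted_control_rate(co, flat_curve(), t_ref = 20)
  expect_equal(res$control_rate, 2 / 3)
  all_ok <- adjusted_control_rate(
    toy_cohort(c(5, 6, 6.5), rep("KNOWN", 3), t_obs = 20),
    flat_curve(), t_ref = 20)
  expect_equal(all_ok$control_rate, 1.0)
  expect_error(
    adjusted_control_rate(toy_cohort(5, "NFG", 20), flat_curve(), 20),
    class = "thermoglyc_undefined_rate")
})

test_that("missing subgroup curves raise a configuration error", {
  co <- toy_cohort(c(5, 8), c("NFG", "KNOWN"), t_obs = 20)
  expect_error(adjusted_prevalence(co, list(NFG = flat_curve()), 20),
               class = "thermoglyc_config_error")
})

test_that("adjusting everyone to their own survey temperature is the identity", {
  set.seed(61)
  fpg <- runif(400, 4, 10)
  diagnosed <- runif(400) < 0.1
  co <- toy_cohort(fpg, as.character(classify_t2dm(fpg, diagnosed)),
                   t_obs = runif(400, 5, 30))
  curves <- list(NFG = toy_curve(function(t) 0.02 * (30 - t)^1.5 / 5),
                 KNOWN = toy_curve(function(t) 1.34 / 625 * (30 - t)^2),
                 NEWLY_DETECTED = toy_curve(function(t) 0.003 * (t - 19)^2))
  res <- adjusted_prevalence(co, curves, t_ref = co$tmean_lag0)
  expect_equal(res$adjusted_fpg, co$fpg1, tolerance = 1e-12)
  crude <- mean(co$subgroup %in% c("KNOWN", "NEWLY_DETECTED") |
                  co$fpg1 >= 7)
  expect_equal(res$prevalence, crude, tolerance = 1e-12)
  known <- co$subgroup == "KNOWN"
  ctrl <- adjusted_control_rate(co, curves$KNOWN,
                                t_ref = co$tmean_lag0[known])
  expect_equal(ctrl$control_rate, mean(co$fpg1[known] < 7),
               tolerance = 1e-12)
})

test_that("monotone decreasing curve implies nondecreasing control rate", {
  set.seed(62)
  co <- toy_cohort(runif(200, 5, 11), rep("KNOWN", 200),
                   t_obs = runif(200, 5, 30))
  curve <- toy_curve(function(t) 1.2 / 625 * (30 - t)^2)
  rates <- vapply(c(5, 10, 15, 20, 22.5, 25, 30), function(tr) {
    adjusted_control_rate(co, curve, tr)$control_rate
  }, numeric(1))
  expect_true(all(diff(rates) >= 0))
})

test_that("adjustment is a rigid shift preserving within-stratum ranks", {
  set.seed(63)
  co <- toy_cohort(runif(50, 4, 11), rep("KNOWN", 50), t_obs = 12)
  curve <- toy_curve(function(t) 1.34 / 625 * (30 - t)^2)
  res <- adjusted_prevalence(co, list(KNOWN = curve), t_ref = 25)
  expect_equal(order(res$adjusted_fpg), order(co$fpg1))
  # linearity: mean adjusted FPG equals mean(fpg) - mean(delta)
  d <- delta_fpg(curve, co$tmean_lag0, 25)
  expect_equal(unname(res$mean_adjusted_fpg["KNOWN"]),
               mean(co$fpg1) - mean(d), tolerance = 1e-12)
})

test_that("a flat truth gives an adjustment profile constant in the reference", {
  co <- toy_cohort(c(runif(30, 4, 6.5), 8.2, 9.0, 7.4),
                   c(rep("NFG", 30), "KNOWN", "KNOWN", "NEWLY_DETECTED"),
                   t_obs = runif(33, 5, 30))
  curves <- list(NFG = flat_curve(), KNOWN = flat_curve(),
                 NEWLY_DETECTED = flat_curve())
  prof <- adjustment_profile(co, curves)
  expect_equal(nrow(prof), 7)
  expect_equal(length(unique(prof$prevalence_pct)), 1)
  expect_equal(length(unique(prof$control_rate_pct)), 1)
  expect_equal(length(unique(prof$mean_fpg_total)), 1)
})

test_that("a planted U-shaped curve yields a dip-shaped prevalence profile", {
  set.seed(64)
  n <- 12000
  t_obs <- runif(n, 5, 30)
  vertex <- 20
  curves <- list(
    NFG = toy_curve(function(t) 0.10 / 625 * (30 - t)^2),
    KNOWN = toy_curve(function(t) 1.34 / 625 * (30 - t)^2),
    NEWLY_DETECTED = toy_curve(function(t) 0.004 * (t - vertex)^2))
  subgroup <- sample(c("NFG", "KNOWN", "NEWLY_DETECTED"), n, TRUE,
                     prob = c(0.906, 0.035, 0.059))
  # FPG generated on each subgroup's own curve so that undiagnosed people
  # near the threshold move across it as the reference moves
  base <- c(NFG = 6.2, KNOWN = 8.3, NEWLY_DETECTED = 7.1)
  fpg <- base[subgroup] +
    vapply(seq_len(n),
           function(i) curves[[subgroup[i]]]$delta[
             findInterval(t_obs[i], curves[[subgroup[i]]]$temp)],
           numeric(1)) + rnorm(n, 0, 0.35)
  co <- toy_cohort(pmax(fpg, 1), subgroup, t_obs)
  prof <- adjustment_profile(co, curves)
  best <- prof$t_ref[which.min(prof$prevalence_pct)]
  expect_lte(abs(best - vertex), 2.5)
  expect_gt(prof$prevalence_pct[prof$t_ref == 5],
            min(prof$prevalence_pct))
  expect_gt(prof$prevalence_pct[prof$t_ref == 30],
            min(prof$prevalence_pct))
})
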