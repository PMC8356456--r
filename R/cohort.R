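# Cohort builder: WHO-2006 diabetes classification, derived covariates,
# and descriptive summaries (monthly series and a Table-1 style description
# with between-subgroup tests).

#' Classify participants into diabetes subgroups (WHO 2006)
#'
#' Physician-diagnosed participants are `KNOWN` regardless of their current
#' FPG. Undiagnosed participants with FPG >= 7.0 mmol/L (or, when
#' `use_2h = TRUE`, 2-h plasma glucose >= 11.1 mmol/L) are `NEWLY_DETECTED`;
#' the remaining undiagnosed participants are `NFG` (normal fasting
#' glucose). Thresholds are compared at full floating-point precision and
#' the 7.0 boundary is inclusive.
#'
#' Undiagnosed participants who report hypoglycemic-medicine use do not fit
#' the NFG definition (which excludes hypoglycemic use) and are returned as
#' `NA` with a data-consistency warning; callers may reassign them.
#'
#' @param fpg1 fasting plasma glucose, mmol/L.
#' @param diagnosed logical, physician-diagnosed diabetes.
#' @param med logical, hypoglycemic-medicine use (default `FALSE`).
#' @param pg_2h optional 2-h plasma glucose, mmol/L.
#' @param use_2h also classify on 2-h glucose >= 11.1 mmol/L.
#' @return factor with levels `NFG`, `KNOWN`, `NEWLY_DETECTED`.
#' @export
classify_t2dm <- function(fpg1, diagnosed, med = FALSE, pg_2h = NULL,
                          use_2h = FALSE) {
  n <- length(fpg1)
  med <- rep_len(med, n)
  diagnosed <- rep_len(diagnosed, n)
  if (any(is.na(fpg1))) {
    stop_thermoglyc("fpg1 must be present for every participant",
                    "thermoglyc_validation_error")
  }
  if (use_2h && (is.null(pg_2h) || anyNA(pg_2h))) {
    stop_thermoglyc("use_2h = TRUE requires pg_2h for every participant",
                    "thermoglyc_validation_error")
  }
  high <- fpg1 >= 7.0
  if (use_2h) high <- high | pg_2h >= 11.1
  out <- ifelse(diagnosed, "KNOWN", ifelse(high, "NEWLY_DETECTED", "NFG"))
  inconsistent <- !diagnosed & med
  if (any(inconsistent)) {
    warning(sprintf(
      "%d undiagnosed participant(s) report hypoglycemic-medicine use; set to NA",
      sum(inconsistent)), call. = FALSE)
    out[inconsistent] <- NA_character_
  }
  factor(out, levels = c("NFG", "KNOWN", "NEWLY_DETECTED"))
}

#' Classify a cohort table
#'
#' Adds a `subgroup` column via [classify_t2dm()]. Undiagnosed
#' medicine-users (classified `NA`) are dropped with a message; their count
#' is stored in `attr(, "n_dropped_med")`.
#'
#' @param cohort participant data.frame (columns `fpg1`, `diagnosed_t2dm`,
#'   `hypoglycemic_med`, optionally `pg_2h`).
#' @param use_2h passed to [classify_t2dm()].
#' @return classified cohort.
#' @export
classify_cohort <- function(cohort, use_2h = FALSE) {
  cohort$subgroup <- withCallingHandlers(
    classify_t2dm(cohort$fpg1, cohort$diagnosed_t2dm,
                  cohort$hypoglycemic_med %||% FALSE,
                  pg_2h = cohort$pg_2h, use_2h = use_2h),
    warning = function(w) invokeRestart("muffleWarning"))
  dropped <- sum(is.na(cohort$subgroup))
  if (dropped > 0) {
    message(sprintf("dropping %d undiagnosed hypoglycemic-medicine user(s)",
                    dropped))
    cohort <- cohort[!is.na(cohort$subgroup), , drop = FALSE]
  }
  attr(cohort, "n_dropped_med") <- dropped
  cohort
}

#' Body mass index and its category
#'
#' BMI = weight / height^2. Categories use the bins `<18.5`, `18.5-23.9`,
#' `24.0-27.9`, `>=28` kg/m^2 with inclusive lower bounds.
#'
#' @param weight kg.
#' @param height m.
#' @return data.frame with `bmi` (kg/m^2) and `bmi_category` (factor).
#' @export
compute_bmi <- function(weight, height) {
  if (any(!is.finite(weight)) || any(!is.finite(height)) ||
      any(weight <= 0) || any(height <= 0)) {
    stop_thermoglyc("weight and height must be positive",
                    "thermoglyc_validation_error")
  }
  bmi <- weight / height^2
  category <- cut(bmi, breaks = c(-Inf, 18.5, 24, 28, Inf),
                  labels = c("<18.5", "18.5-23.9", "24.0-27.9", ">=28"),
                  right = FALSE)
  data.frame(bmi = bmi, bmi_category = category)
}

se_mean <- function(x) if (length(x) > 1) sd(x) / sqrt(length(x)) else 0

#' Monthly FPG and temperature summary
#'
#' Mean and standard error of FPG and of daily mean temperature (lag 0) per
#' calendar month, per subgroup and for the whole cohort. Months without
#' data are omitted.
#'
#' @param cohort classified cohort with `subgroup`, `fpg1` and a lag-0
#'   temperature column.
#' @param temp column holding the survey-day temperature.
#' @return data.frame with `month`, `subgroup`, `n`, `fpg_mean`, `fpg_se`,
#'   `temp_mean`, `temp_se`.
#' @export
monthly_summary <- function(cohort, temp = "tmean_lag0") {
  if (nrow(cohort) == 0) {
    return(data.frame(month = integer(), subgroup = character(),
                      n = integer(), fpg_mean = numeric(),
                      fpg_se = numeric(), temp_mean = numeric(),
                      temp_se = numeric()))
  }
  stopifnot("subgroup" %in% names(cohort), temp %in% names(cohort))
  month <- as.integer(strftime(cohort$survey_date, "%m"))
  groups <- c(levels(cohort$subgroup), "Total")
  out <- list()
  for (g in groups) {
    sel <- if (g == "Total") rep(TRUE, nrow(cohort)) else cohort$subgroup == g
    for (m in sort(unique(month[sel]))) {
      i <- sel & month == m
      if (!any(i)) next
      out[[length(out) + 1L]] <- data.frame(
        month = m, subgroup = g, n = sum(i),
        fpg_mean = mean(cohort$fpg1[i]), fpg_se = se_mean(cohort$fpg1[i]),
        temp_mean = mean(cohort[[temp]][i]),
        temp_se = se_mean(cohort[[temp]][i]),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

# Normality gate for the display form of a continuous variable: Shapiro-Wilk
# on a subsample of at most 5000 values at alpha = 0.05. Presentation only.
.looks_normal <- function(x, seed = 1L) {
  x <- x[!is.na(x)]
  if (length(x) < 8 || sd(x) == 0) return(FALSE)
  if (length(x) > 5000) {
    x <- with_stream(seed, 41L, sample(x, 5000))
  }
  shapiro.test(x)$p.value >= 0.05
}

#' Table-1 style cohort description with subgroup tests
#'
#' Counts and percentages per subgroup for categorical variables with
#' chi-square tests, and per-subgroup summaries for continuous variables
#' with Kruskal-Wallis tests. Continuous variables that pass a Shapiro-Wilk
#' normality gate are displayed as mean (SD), otherwise median (25th-75th
#' percentile); the gate affects display only, not the test. Subgroups with
#' zero members cause tests to be skipped with a notice.
#'
#' @param cohort classified cohort.
#' @param categorical,continuous variable names to summarize (defaults:
#'   the standard roster variables present in `cohort`).
#' @return list with elements `counts` (subgroup n and percent),
#'   `categorical` and `continuous` data.frames, and `tests_skipped`.
#' @export
describe_cohort <- function(cohort,
                            categorical = intersect(
                              c("sex", "education", "career", "smoking",
                                "drinking", "bmi_category",
                                "hypoglycemic_med"), names(cohort)),
                            continuous = intersect(
                              c("age", "bmi", "physical_activity",
                                "sedentary_time", "humidity_lag0"),
                              names(cohort))) {
  stopifnot("subgroup" %in% names(cohort))
  sub <- factor(cohort$subgroup, levels = c("NFG", "KNOWN", "NEWLY_DETECTED"))
  n_total <- nrow(cohort)
  counts <- as.data.frame(table(subgroup = sub), stringsAsFactors = FALSE)
  names(counts)[2] <- "n"
  counts$percent <- round(100 * counts$n / n_total, 1)
  tests_skipped <- any(counts$n == 0)
  if (tests_skipped) {
    message("subgroup(s) with zero members: between-group tests skipped")
  }

  cat_rows <- list()
  for (v in categorical) {
    x <- cohort[[v]]
    if (is.logical(x)) x <- ifelse(x, "yes", "no")
    tab <- table(x, sub)
    p <- if (!tests_skipped && nrow(tab) > 1) {
      suppressWarnings(chisq.test(tab)$p.value)
    } else NA_real_
    for (lev in rownames(tab)) {
      row <- data.frame(variable = v, level = lev,
                        stringsAsFactors = FALSE)
      for (g in colnames(tab)) {
        row[[paste0("n_", g)]] <- tab[lev, g]
        row[[paste0("pct_", g)]] <-
          round(100 * tab[lev, g] / sum(tab[, g]), 1)
      }
      row$n_total <- sum(tab[lev, ])
      row$pct_total <- round(100 * sum(tab[lev, ]) / sum(tab), 1)
      row$p_value <- p
      cat_rows[[length(cat_rows) + 1L]] <- row
    }
  }

  cont_rows <- list()
  for (v in continuous) {
    x <- cohort[[v]]
    normal <- .looks_normal(x)
    p <- if (!tests_skipped) {
      kruskal.test(x, sub)$p.value
    } else NA_real_
    row <- data.frame(variable = v,
                      display = if (normal) "mean_sd" else "median_iqr",
                      stringsAsFactors = FALSE)
    for (g in c(levels(sub), "Total")) {
      xi <- if (g == "Total") x else x[sub == g]
      xi <- xi[!is.na(xi)]
      if (length(xi) == 0) {
        row[[paste0("summary_", g)]] <- NA_character_
        next
      }
      row[[paste0("summary_", g)]] <- if (normal) {
        sprintf("%.1f (%.1f)", mean(xi), sd(xi))
      } else {
        q <- quantile(xi, c(0.25, 0.5, 0.75), names = FALSE)
        sprintf("%.1f (%.1f-%.1f)", q[2], q[1], q[3])
      }
    }
    row$p_value <- p
    cont_rows[[length(cont_rows) + 1L]] <- row
  }

  list(counts = counts,
       categorical = if (length(cat_rows)) do.call(rbind, cat_rows) else NULL,
       continuous = if (length(cont_rows)) do.call(rbind, cont_rows) else NULL,
       tests_skipped = tests_skipped)
}
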