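# End-to-end pipeline: synthetic (or user-supplied) station weather and
# survey roster -> district exposure series + cross-validation -> lagged
# exposures -> WHO-2006 classification and descriptives -> per-subgroup
# temperature-response fits, curves and contrasts -> interaction test ->
# adjustment profile. All outputs are plain-text tables plus a JSON
# manifest with checksums; a fixed seed makes synthetic runs bit-identical.

#' Configure a pipeline run
#'
#' Exactly one of `stations_csv`/`roster_csv` (user data) or
#' `truth`/`weather` specs (synthetic data) must be supplied.
#'
#' @param truth a [truth_spec()] for synthetic runs.
#' @param weather a [weather_field_spec()] for synthetic runs.
#' @param n,n_districts synthetic cohort size and district count.
#' @param stations_csv,roster_csv paths to user-supplied delimited tables.
#' @param power IDW power.
#' @param cv_folds folds for interpolation cross-validation (0 to skip).
#' @param max_lag largest exposure lag, days.
#' @param lags lags at which subgroup models are fitted.
#' @param k temperature basis dimension.
#' @param model2 also fit the extended covariate model (adds sunlight and
#'   precipitation) for the total population.
#' @param use_2h classify on FPG plus 2-h plasma glucose.
#' @param refs reference temperatures for the adjustment profile.
#' @param contrast_cold,contrast_warm,contrast_vertex temperatures (degrees
#'   C) used for the reported contrasts: cold-vs-warm for monotone-curve
#'   subgroups, cold/warm-vs-vertex for the newly detected subgroup.
#' @param seed master seed (mandatory for synthetic runs).
#' @return object of class `thermoglyc_config`.
#' @export
run_config <- function(truth = NULL, weather = NULL, n = 5000,
                       n_districts = 21,
                       stations_csv = NULL, roster_csv = NULL,
                       power = 2, cv_folds = 10, max_lag = 6,
                       lags = 0, k = 3, model2 = FALSE, use_2h = FALSE,
                       refs = c(5, 10, 15, 20, 22.5, 25, 30),
                       contrast_cold = 5, contrast_warm = 30,
                       contrast_vertex = 19,
                       seed = NULL) {
  synthetic <- !is.null(truth) || !is.null(weather)
  from_files <- !is.null(stations_csv) || !is.null(roster_csv)
  if (synthetic == from_files) {
    stop_thermoglyc(
      "supply either synthetic specs (truth + weather) or input paths, not both",
      "thermoglyc_config_error")
  }
  if (synthetic) {
    stopifnot(inherits(truth, "truth_spec"),
              inherits(weather, "weather_field_spec"))
    if (is.null(seed)) {
      stop_thermoglyc("seed is mandatory for synthetic runs",
                      "thermoglyc_config_error")
    }
  } else {
    stopifnot(!is.null(stations_csv), !is.null(roster_csv))
  }
  structure(
    list(truth = truth, weather = weather, n = n, n_districts = n_districts,
         stations_csv = stations_csv, roster_csv = roster_csv,
         power = power, cv_folds = cv_folds, max_lag = max_lag,
         lags = lags, k = k, model2 = model2, use_2h = use_2h, refs = refs,
         contrast_cold = contrast_cold, contrast_warm = contrast_warm,
         contrast_vertex = contrast_vertex,
         seed = seed, synthetic = synthetic),
    class = "thermoglyc_config")
}

#' Read a pipeline configuration from YAML
#'
#' Synthetic specs are given under `truth:` and `weather:` keys using the
#' [truth_spec()] / [weather_field_spec()] argument names; every other key
#' maps directly to a [run_config()] argument.
#'
#' @param path YAML file.
#' @return `thermoglyc_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$truth)) {
    tr <- y$truth
    y$truth <- truth_spec(
      subgroup_mix = if (is.null(tr$subgroup_mix)) {
        eval(formals(truth_spec)$subgroup_mix)
      } else unlist(tr$subgroup_mix),
      curve_params = if (is.null(tr$curve_params)) {
        eval(formals(truth_spec)$curve_params)
      } else lapply(tr$curve_params, as.numeric),
      baseline_fpg = if (is.null(tr$baseline_fpg)) {
        eval(formals(truth_spec)$baseline_fpg)
      } else unlist(tr$baseline_fpg),
      covariate_effects = tr$covariate_effects %||%
        eval(formals(truth_spec)$covariate_effects),
      district_sd = tr$district_sd %||% 0.15,
      resid_sd = tr$resid_sd %||% 0.8,
      seed = tr$seed %||% y$seed %||% 1L)
  }
  if (!is.null(y$weather)) {
    w <- y$weather
    args <- w[intersect(names(w), names(formals(weather_field_spec)))]
    if (!is.null(args$date_start)) args$date_start <- as.Date(args$date_start)
    if (!is.null(args$date_end)) args$date_end <- as.Date(args$date_end)
    y$weather <- do.call(weather_field_spec, args)
  }
  do.call(run_config, y[intersect(names(y), names(formals(run_config)))])
}

.write_artifact <- function(x, dir, name) {
  path <- file.path(dir, name)
  write.csv(x, path, row.names = FALSE)
  path
}

#' Run the full pipeline
#'
#' Executes every stage in order and writes all result tables, a markdown
#' report and a JSON manifest (file names + MD5 checksums) to `out_dir`.
#' Stage failures abort with the stage name; artifacts written before the
#' failure are retained.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created if needed).
#' @return (invisibly) list of in-memory artifacts: `cohort`, `cv_report`,
#'   `description`, `monthly`, `fits`, `curves`, `contrasts`, `aic_table`,
#'   `interaction`, `profile`, `manifest`.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "thermoglyc_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop_thermoglyc(sprintf("stage '%s' failed: %s", name,
                              conditionMessage(e)),
                      "thermoglyc_stage_error", stage = name)
    })
  }

  # -- data -----------------------------------------------------------------
  dat <- stage("input", {
    if (config$synthetic) {
      stations <- gen_station_weather(config$weather)
      roster <- gen_cohort(config$truth, stations, config$n,
                           config$n_districts, seed = config$seed)
      list(stations = stations, roster = roster)
    } else {
      list(stations = read_table_csv(config$stations_csv),
           roster = read_table_csv(config$roster_csv))
    }
  })

  # -- exposure -------------------------------------------------------------
  districts <- unique(dat$roster[c("district_id", "district_lon",
                                   "district_lat")])
  names(districts) <- c("district_id", "lon", "lat")
  exposure <- stage("exposure", {
    dates <- seq(min(dat$roster$survey_date) - config$max_lag,
                 max(dat$roster$survey_date), by = "day")
    series <- district_exposure_series(dat$stations, districts,
                                       dates = dates, power = config$power)
    cv <- if (config$cv_folds >= 2) {
      crossvalidate_interpolation(dat$stations, k = config$cv_folds,
                                  power = config$power,
                                  seed = config$seed %||% 1L)
    } else NULL
    list(series = series, cv = cv)
  })

  # -- cohort ---------------------------------------------------------------
  cohort <- stage("cohort", {
    x <- assign_exposures(dat$roster, exposure$series,
                          max_lag = config$max_lag)
    x <- cbind(x, compute_bmi(x$weight, x$height)["bmi_category"])
    classify_cohort(x, use_2h = config$use_2h)
  })
  description <- stage("describe", describe_cohort(cohort))
  monthly <- stage("monthly", monthly_summary(cohort))

  # -- models ---------------------------------------------------------------
  subgroups <- c("total", intersect(c("NFG", "KNOWN", "NEWLY_DETECTED"),
                                    unique(as.character(cohort$subgroup))))
  fits <- list(); curves <- list(); contrasts <- list(); aic_rows <- list()
  stage("fit", {
    for (sg in subgroups) {
      for (lag in config$lags) {
        sp <- model_spec(lag = lag, k = config$k, subgroup = sg)
        fit <- suppressMessages(fit_fpg_model(cohort, sp))
        key <- paste0(sg, "_lag", lag)
        fits[[key]] <- fit
        aic_rows[[key]] <- data.frame(subgroup = sg, lag = lag,
                                       model = "main", aic = fit$aic,
                                       n = fit$n_obs)
        curve <- extract_response_curve(fit)
        curves[[key]] <- curve
        lo <- max(config$contrast_cold, fit$temp_range[1])
        hi <- min(config$contrast_warm, fit$temp_range[2])
        vx <- min(max(config$contrast_vertex, lo), hi)
        ctr <- if (sg == "NEWLY_DETECTED") {
          rbind(estimate_contrast(fit, lo, vx),
                estimate_contrast(fit, hi, vx))
        } else {
          estimate_contrast(fit, lo, hi)
        }
        ctr$model <- "main"
        contrasts[[key]] <- ctr
      }
    }
    if (config$model2) {
      sp2 <- model_spec(lag = 0, k = config$k, subgroup = "total",
                        extra_terms = c("sunlight_lag0",
                                        "precipitation_lag0"))
      fit2 <- suppressMessages(fit_fpg_model(cohort, sp2))
      fits[["total_model2"]] <- fit2
      aic_rows[["total_model2"]] <- data.frame(subgroup = "total", lag = 0,
                                                model = "model2",
                                                aic = fit2$aic,
                                                n = fit2$n_obs)
      ctr2 <- estimate_contrast(fit2,
                                max(config$contrast_cold,
                                    fit2$temp_range[1]),
                                min(config$contrast_warm,
                                    fit2$temp_range[2]))
      ctr2$model <- "model2"
      contrasts[["total_model2"]] <- ctr2
    }
  })
  aic_table <- do.call(rbind, aic_rows)

  interaction <- stage("interaction", {
    if (length(subgroups) > 2) test_interaction(cohort) else NULL
  })

  # -- adjustment -----------------------------------------------------------
  profile <- stage("adjustment", {
    lag0 <- paste0(intersect(c("NFG", "KNOWN", "NEWLY_DETECTED"), subgroups),
                   "_lag", config$lags[1])
    cl <- curves[lag0]
    names(cl) <- sub("_lag.*", "", names(cl))
    adjustment_profile(cohort, cl, refs = config$refs,
                       exposure = paste0("tmean_lag", config$lags[1]))
  })

  # -- outputs --------------------------------------------------------------
  files <- character()
  files["cohort"] <- .write_artifact(cohort, out_dir, "cohort.csv")
  if (!is.null(exposure$cv)) {
    files["cv_report"] <- .write_artifact(exposure$cv, out_dir,
                                          "cv_report.csv")
  }
  files["monthly"] <- .write_artifact(monthly, out_dir,
                                      "monthly_summary.csv")
  files["subgroup_counts"] <- .write_artifact(description$counts, out_dir,
                                              "subgroup_counts.csv")
  if (!is.null(description$categorical)) {
    files["table1_categorical"] <- .write_artifact(
      description$categorical, out_dir, "table1_categorical.csv")
  }
  if (!is.null(description$continuous)) {
    files["table1_continuous"] <- .write_artifact(
      description$continuous, out_dir, "table1_continuous.csv")
  }
  for (key in names(curves)) {
    files[paste0("curve_", key)] <- .write_artifact(
      cbind(as.data.frame(curves[[key]]),
            anchor = curve_anchor(curves[[key]])),
      out_dir, sprintf("curve_%s.csv", key))
  }
  files["contrasts"] <- .write_artifact(do.call(rbind, contrasts), out_dir,
                                        "contrasts.csv")
  files["aic_table"] <- .write_artifact(aic_table, out_dir, "aic_table.csv")
  files["adjustment_profile"] <- .write_artifact(profile, out_dir,
                                                 "adjustment_profile.csv")
  if (!is.null(interaction)) {
    jsonlite::write_json(interaction[c("p_value", "statistic", "df",
                                       "aic_shared", "aic_interaction")],
                         file.path(out_dir, "interaction.json"),
                         auto_unbox = TRUE, digits = NA)
    files["interaction"] <- file.path(out_dir, "interaction.json")
  }

  artifacts <- list(cohort = cohort, cv_report = exposure$cv,
                    description = description, monthly = monthly,
                    fits = fits, curves = curves,
                    contrasts = do.call(rbind, contrasts),
                    aic_table = aic_table, interaction = interaction,
                    profile = profile, out_dir = out_dir, files = files,
                    n_dropped_med = attr(cohort, "n_dropped_med") %||% 0)
  files["report"] <- write_report(artifacts,
                                  file.path(out_dir, "report.md"))

  manifest <- data.frame(
    artifact = names(files), file = basename(unlist(files)),
    md5 = unname(tools::md5sum(unlist(files))), row.names = NULL)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  artifacts$manifest <- manifest
  invisible(artifacts)
}

fmt_tab <- function(df, digits = 3) {
  df <- as.data.frame(df)
  for (i in seq_along(df)) {
    if (is.numeric(df[[i]])) df[[i]] <- signif(df[[i]], digits)
  }
  header <- paste(names(df), collapse = " | ")
  sep <- paste(rep("---", ncol(df)), collapse = " | ")
  rows <- apply(df, 1, paste, collapse = " | ")
  paste(c(paste("|", header, "|"), paste("|", sep, "|"),
          paste("|", rows, "|")), collapse = "\n")
}

#' Write a human-readable run report
#'
#' Markdown summary of a completed [run_pipeline()] run: subgroup counts,
#' descriptive tables, interpolation cross-validation metrics, per-subgroup
#' temperature contrasts, the interaction test and the adjustment profile.
#' Sections whose artifact was not produced are marked "not run".
#'
#' @param artifacts list returned by [run_pipeline()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_report <- function(artifacts, path) {
  sec <- function(title, body) c(paste("##", title), "", body, "")
  lines <- c("# Temperature-FPG pipeline report", "")
  lines <- c(lines, sec("Cohort",
    c(sprintf("%d participants; %d undiagnosed medicine user(s) excluded.",
              nrow(artifacts$cohort), artifacts$n_dropped_med),
      "", fmt_tab(artifacts$description$counts))))
  lines <- c(lines, sec("Interpolation cross-validation",
    if (is.null(artifacts$cv_report)) "not run"
    else fmt_tab(artifacts$cv_report)))
  anchors <- data.frame(
    model = names(artifacts$curves),
    anchor_temp = vapply(artifacts$curves, curve_anchor, numeric(1)))
  lines <- c(lines, sec("Minimum-FPG (anchor) temperatures", fmt_tab(anchors)))
  lines <- c(lines, sec("Temperature contrasts (mmol/L)",
                        fmt_tab(artifacts$contrasts)))
  lines <- c(lines, sec("Temperature x status interaction",
    if (is.null(artifacts$interaction)) "not run"
    else sprintf("F = %.2f on %.1f df, p = %.3g (AIC shared %.1f vs interaction %.1f)",
                 artifacts$interaction$statistic, artifacts$interaction$df,
                 artifacts$interaction$p_value,
                 artifacts$interaction$aic_shared,
                 artifacts$interaction$aic_interaction)))
  lines <- c(lines, sec("Adjustment profile", fmt_tab(artifacts$profile)))
  writeLines(lines, path)
  invisible(path)
}
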