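#' Specify a synthetic weather field
#'
#' Describes a network of weather stations over a lon/lat rectangle together
#' with a seasonal temperature cycle, a linear spatial gradient, and
#' station-day noise. [gen_station_weather()] turns the specification into
#' daily station records.
#'
#' The daily mean temperature at station \eqn{s} on day \eqn{d} is
#' \deqn{T(s,d) = \mu + A \cos(2\pi (doy(d) - p)/365.25)
#'   + g_{lon}(lon_s - lon_0) + g_{lat}(lat_s - lat_0) + \epsilon_{sd}}
#' with \eqn{\epsilon_{sd} \sim N(0, \sigma^2)} and \eqn{(lon_0, lat_0)} the
#' bounding-box centre. The warm peak of the cycle falls on day-of-year `p`
#' (default 196, mid July, so January is coldest as in a Northern-hemisphere
#' subtropical province).
#'
#' @param n_stations number of stations (>= 1).
#' @param bbox numeric vector `c(lon_min, lon_max, lat_min, lat_max)` degrees.
#' @param date_start,date_end inclusive `Date` range of daily records.
#' @param seasonal_mean annual mean of daily mean temperature, degrees C.
#' @param seasonal_amplitude half-range of the seasonal cycle, degrees C (>= 0).
#' @param gradient_lon,gradient_lat linear spatial gradient, degrees C per
#'   degree longitude/latitude.
#' @param noise_sd SD of independent station-day temperature noise, degrees C.
#' @param peak_doy day-of-year of the warm peak of the seasonal cycle.
#' @param diurnal_spread typical half-distance between tmean and tmin/tmax,
#'   degrees C; per-day spreads are folded-normal draws around it so
#'   `tmin <= tmean <= tmax` always holds.
#' @param humidity_mean,humidity_sd relative humidity distribution, percent
#'   (values are clamped to \[0, 100\]).
#' @param humidity_coupling percent humidity per degree C: humidity tracks
#'   the deterministic (seasonal + spatial) part of temperature, as in a
#'   monsoon climate where the warm season is also the humid season.
#' @param sunlight_mean,sunlight_sd sunlight hours/day (clamped at 0).
#' @param precip_wet_prob probability a station-day is wet.
#' @param precip_mean mean rainfall on wet days, mm (exponential).
#' @param seed integer master seed; every random component derives its own
#'   stream from it, so regenerating with the same spec is byte-identical.
#' @return an object of class `weather_field_spec`.
#' @seealso [gen_station_weather()]
#' @export
weather_field_spec <- function(n_stations = 86,
                               bbox = c(110, 117, 20.5, 25.5),
                               date_start = as.Date("2013-10-01"),
                               date_end = as.Date("2014-05-31"),
                               seasonal_mean = 19,
                               seasonal_amplitude = 10,
                               gradient_lon = 0,
                               gradient_lat = -1.2,
                               noise_sd = 1.2,
                               peak_doy = 196,
                               diurnal_spread = 3.5,
                               humidity_mean = 75, humidity_sd = 10,
                               humidity_coupling = 1,
                               sunlight_mean = 5, sunlight_sd = 2,
                               precip_wet_prob = 0.35, precip_mean = 8,
                               seed = 1L) {
  date_start <- as.Date(date_start); date_end <- as.Date(date_end)
  if (n_stations < 1) {
    stop_thermoglyc("n_stations must be >= 1", "thermoglyc_config_error")
  }
  if (date_end < date_start) {
    stop_thermoglyc("empty date range", "thermoglyc_config_error")
  }
  if (seasonal_amplitude < 0 || noise_sd < 0) {
    stop_thermoglyc("amplitude and noise_sd must be >= 0",
                    "thermoglyc_config_error")
  }
  stopifnot(length(bbox) == 4, bbox[2] >= bbox[1], bbox[4] >= bbox[3])
  structure(
    list(n_stations = as.integer(n_stations), bbox = bbox,
         date_start = date_start, date_end = date_end,
         seasonal_mean = seasonal_mean,
         seasonal_amplitude = seasonal_amplitude,
         gradient_lon = gradient_lon, gradient_lat = gradient_lat,
         noise_sd = noise_sd, peak_doy = peak_doy,
         diurnal_spread = diurnal_spread,
         humidity_mean = humidity_mean, humidity_sd = humidity_sd,
         humidity_coupling = humidity_coupling,
         sunlight_mean = sunlight_mean, sunlight_sd = sunlight_sd,
         precip_wet_prob = precip_wet_prob, precip_mean = precip_mean,
         seed = as.integer(seed)),
    class = "weather_field_spec"
  )
}

#' Generate daily station weather records
#'
#' Draws station coordinates uniformly in the bounding box and simulates one
#' record per station per day under the generative model documented in
#' [weather_field_spec()]. Each random component (station placement,
#' temperature noise, diurnal spreads, humidity, sunlight, precipitation)
#' uses its own RNG stream derived from `spec$seed`, so e.g. changing the
#' humidity parameters does not perturb the temperature draws.
#'
#' @param spec a [weather_field_spec()].
#' @return data.frame with columns `station_id`, `lon`, `lat`, `date`,
#'   `tmean`, `tmin`, `tmax`, `humidity`, `sunlight`, `precipitation`;
#'   one row per station-day, satisfying `tmin <= tmean <= tmax` and
#'   `humidity` in \[0, 100\].
#' @export
gen_station_weather <- function(spec) {
  stopifnot(inherits(spec, "weather_field_spec"))
  dates <- seq(spec$date_start, spec$date_end, by = "day")
  ns <- spec$n_stations
  seed <- spec$seed

  lon <- with_stream(seed, 1L, runif(ns, spec$bbox[1], spec$bbox[2]))
  lat <- with_stream(seed, 2L, runif(ns, spec$bbox[3], spec$bbox[4]))
  lon0 <- mean(spec$bbox[1:2]); lat0 <- mean(spec$bbox[3:4])

  grid <- expand.grid(station = seq_len(ns), date = dates,
                      KEEP.OUT.ATTRS = FALSE)
  doy <- as.integer(strftime(grid$date, "%j"))
  seasonal <- spec$seasonal_mean +
    spec$seasonal_amplitude * cos(2 * pi * (doy - spec$peak_doy) / 365.25)
  spatial <- spec$gradient_lon * (lon[grid$station] - lon0) +
    spec$gradient_lat * (lat[grid$station] - lat0)
  nrec <- nrow(grid)
  noise <- with_stream(seed, 3L, rnorm(nrec, 0, spec$noise_sd))
  tmean <- seasonal + spatial + noise

  spread_lo <- with_stream(seed, 4L, abs(rnorm(nrec, spec$diurnal_spread, 1)))
  spread_hi <- with_stream(seed, 5L, abs(rnorm(nrec, spec$diurnal_spread, 1)))
  hum_centre <- spec$humidity_mean +
    (spec$humidity_coupling %||% 0) * (seasonal + spatial -
                                         spec$seasonal_mean)
  humidity <- with_stream(
    seed, 6L, pmin(100, pmax(0, rnorm(nrec, hum_centre,
                                      spec$humidity_sd))))
  sunlight <- with_stream(
    seed, 7L, pmax(0, rnorm(nrec, spec$sunlight_mean, spec$sunlight_sd)))
  precip <- with_stream(seed, 8L, {
    wet <- rbinom(nrec, 1, spec$precip_wet_prob)
    wet * rexp(nrec, rate = 1 / spec$precip_mean)
  })

  data.frame(
    station_id = sprintf("S%03d", grid$station),
    lon = lon[grid$station], lat = lat[grid$station],
    date = grid$date,
    tmean = tmean, tmin = tmean - spread_lo, tmax = tmean + spread_hi,
    humidity = humidity, sunlight = sunlight, precipitation = precip,
    stringsAsFactors = FALSE
  )
}

#' Specify ground truth for a synthetic survey cohort
#'
#' Holds the generative counterpart of the fitted additive model: per-subgroup
#' baseline FPG and temperature-effect curve, additive covariate effects,
#' district random-intercept SD and residual SD. The temperature effect
#' \eqn{f_m(t)} for subgroup \eqn{m} is a polynomial (degree <= 3) in degrees
#' C over `temp_range`, so planted contrasts are analytically known and can
#' be recovered by the model-fitting code in validation studies.
#'
#' Defaults mirror a warm-climate survey population: about 90.6% normal
#' fasting glucose (NFG), 3.5% known diabetes and 5.9% newly detected
#' diabetes; NFG and known curves decrease with temperature (flat near 30
#' degrees C, with cold-vs-warm contrasts f(5) - f(30) of 0.10 and 1.34
#' mmol/L respectively), and the newly detected curve is U-shaped with its
#' vertex at 19 degrees C.
#'
#' @param subgroup_mix named probabilities over `NFG`, `KNOWN`,
#'   `NEWLY_DETECTED`; must sum to 1.
#' @param curve_params named list of polynomial coefficient vectors
#'   `c(c0, c1, c2, ...)` (ascending powers of temperature in degrees C),
#'   one per subgroup; degree at most 3.
#' @param baseline_fpg named baseline FPG (mmol/L) per subgroup, i.e. the
#'   subgroup mean at covariate reference values when `f_m(t) = 0`.
#' @param covariate_effects list with elements `age` (mmol/L per year,
#'   centred at 50), `bmi` (mmol/L per kg/m^2, centred at 23) and
#'   `sex_male` (mmol/L).
#' @param district_sd SD of district random intercepts, mmol/L.
#' @param resid_sd residual SD, mmol/L.
#' @param temp_range temperature range (degrees C) on which the curves are
#'   defined.
#' @param seed integer master seed.
#' @return object of class `truth_spec`.
#' @seealso [gen_cohort()], [truth_curve_value()]
#' @export
truth_spec <- function(subgroup_mix = c(NFG = 0.906, KNOWN = 0.035,
                                        NEWLY_DETECTED = 0.059),
                       curve_params = list(
                         NFG = c(0.10 / 625 * 900, -2 * 0.10 / 625 * 30,
                                 0.10 / 625),
                         KNOWN = c(1.34 / 625 * 900, -2 * 1.34 / 625 * 30,
                                   1.34 / 625),
                         NEWLY_DETECTED = c(0.71 / 196 * 361,
                                            -2 * 0.71 / 196 * 19,
                                            0.71 / 196)),
                       baseline_fpg = c(NFG = 5.2, KNOWN = 7.7,
                                        NEWLY_DETECTED = 8.6),
                       covariate_effects = list(age = 0.008, bmi = 0.02,
                                                sex_male = 0.05),
                       district_sd = 0.15,
                       resid_sd = 0.8,
                       temp_range = c(5, 30),
                       seed = 1L) {
  groups <- c("NFG", "KNOWN", "NEWLY_DETECTED")
  stopifnot(setequal(names(subgroup_mix), groups),
            setequal(names(curve_params), groups),
            setequal(names(baseline_fpg), groups))
  mix <- subgroup_mix[groups]
  if (any(mix < 0) || any(mix > 1) || abs(sum(mix) - 1) > 1e-12) {
    stop_thermoglyc("subgroup_mix must be probabilities summing to 1",
                    "thermoglyc_config_error")
  }
  if (district_sd < 0 || resid_sd < 0) {
    stop_thermoglyc("SDs must be >= 0", "thermoglyc_config_error")
  }
  if (any(vapply(curve_params, length, 1L) > 4L)) {
    stop_thermoglyc("curve polynomials must have degree <= 3",
                    "thermoglyc_config_error")
  }
  structure(
    list(subgroup_mix = mix, curve_params = curve_params[groups],
         baseline_fpg = baseline_fpg[groups],
         covariate_effects = covariate_effects,
         district_sd = district_sd, resid_sd = resid_sd,
         temp_range = temp_range, seed = as.integer(seed)),
    class = "truth_spec"
  )
}

#' Evaluate a truth-spec temperature curve
#'
#' @param truth a [truth_spec()].
#' @param subgroup `"NFG"`, `"KNOWN"` or `"NEWLY_DETECTED"`.
#' @param t temperature(s), degrees C.
#' @return `f_m(t)` in mmol/L.
#' @export
truth_curve_value <- function(truth, subgroup, t) {
  stopifnot(inherits(truth, "truth_spec"),
            subgroup %in% names(truth$curve_params))
  polyval(truth$curve_params[[subgroup]], t)
}

#' Planted temperature contrast of a truth spec
#'
#' `f_m(t_a) - f_m(t_b)`, the ground-truth analogue of [estimate_contrast()].
#'
#' @inheritParams truth_curve_value
#' @param t_a,t_b temperatures, degrees C.
#' @export
truth_contrast <- function(truth, subgroup, t_a, t_b) {
  truth_curve_value(truth, subgroup, t_a) -
    truth_curve_value(truth, subgroup, t_b)
}

# Categorical covariate draws shared by gen_cohort; probabilities are
# loosely matched to a southern-China adult survey population.
.draw_categoricals <- function(n) {
  data.frame(
    sex = sample(c("male", "female"), n, TRUE, prob = c(0.449, 0.551)),
    education = sample(c("junior_or_less", "high_or_college"), n, TRUE,
                       prob = c(0.477, 0.523)),
    career = sample(c("production", "technical", "nonworker"), n, TRUE,
                    prob = c(0.348, 0.361, 0.291)),
    smoking = sample(c("ever", "never"), n, TRUE, prob = c(0.408, 0.592)),
    drinking = sample(c("ever", "never"), n, TRUE, prob = c(0.432, 0.568)),
    stringsAsFactors = FALSE
  )
}

#' Generate a synthetic survey cohort with known ground truth
#'
#' Simulates `n` participants clustered in `n_districts` districts placed in
#' the weather field's bounding box. Each participant receives a survey date,
#' demographic and lifestyle covariates, a diabetes subgroup drawn from
#' `truth$subgroup_mix`, and an FPG generated as
#' \deqn{FPG = baseline_m + f_m(t) + effects(covariates) + \xi_{district}
#'   + \epsilon}
#' where `t` is the inverse-distance-weighted daily mean temperature at the
#' district centroid on the survey date (the same exposure definition the
#' fitting pipeline uses), \eqn{\xi} are Gaussian district intercepts and
#' \eqn{\epsilon} Gaussian residual noise.
#'
#' When `enforce_threshold = TRUE` residuals are resampled so that generated
#' labels are consistent with the WHO fasting-glucose rule by construction:
#' NFG participants end below 7.0 mmol/L and newly detected participants at
#' or above it. Known patients are unconstrained (their label comes from the
#' physician-diagnosis flag, not from FPG).
#'
#' Survey dates are drawn from October through May only, mirroring surveys
#' run outside the hot season; set `full_year = TRUE` to sample all dates.
#'
#' @param truth a [truth_spec()].
#' @param weather station records from [gen_station_weather()].
#' @param n cohort size.
#' @param n_districts number of districts (default 21).
#' @param seed master seed; defaults to `truth$seed`.
#' @param full_year sample survey dates from the whole weather range.
#' @param enforce_threshold resample residuals to make subgroup labels agree
#'   with the 7.0 mmol/L rule (see Details).
#' @param med_use_rate probability a known patient uses hypoglycemic
#'   medicine (default 0.738).
#' @param idw_power inverse-distance weighting power for the exposure truth.
#' @param buffer_days survey dates start this many days after the weather
#'   range opens, so lagged exposures up to this lag exist for everyone.
#' @param districts optional fixed district table (`district_id`, `lon`,
#'   `lat`); when supplied, district placement is not redrawn (useful for
#'   replicate simulations sharing one exposure surface).
#' @param series optional precomputed district exposure series
#'   ([district_exposure_series()] with a `tmean` column) covering all
#'   survey dates; skips the internal interpolation.
#' @return data.frame with one row per participant: identifiers, district
#'   and centroid coordinates, `survey_date`, covariates, `diagnosed_t2dm`,
#'   `hypoglycemic_med`, `fpg1` (mmol/L), and ground-truth columns
#'   `truth_subgroup`, `truth_tsurvey`, `truth_temp_effect`,
#'   `truth_district_effect`.
#' @export
gen_cohort <- function(truth, weather, n, n_districts = 21,
                       seed = truth$seed, full_year = FALSE,
                       enforce_threshold = TRUE, med_use_rate = 0.738,
                       idw_power = 2, buffer_days = 6,
                       districts = NULL, series = NULL) {
  stopifnot(inherits(truth, "truth_spec"), is.data.frame(weather))
  if (n < n_districts || n_districts < 1) {
    stop_thermoglyc("need n >= n_districts >= 1", "thermoglyc_config_error")
  }
  dates <- sort(unique(weather$date))
  # keep a lag buffer at the start so lag 0..buffer_days exposures exist
  dates <- dates[dates >= min(dates) + buffer_days]
  if (length(dates) == 0) {
    stop_thermoglyc("weather range shorter than the lag buffer",
                    "thermoglyc_generation_error")
  }
  if (!full_year) {
    keep <- as.integer(strftime(dates, "%m")) %in% c(10:12, 1:5)
    if (!any(keep)) {
      stop_thermoglyc("weather range contains no October-May dates",
                      "thermoglyc_generation_error")
    }
    dates <- dates[keep]
  }

  # districts: centroids inside the station bounding box
  if (is.null(districts)) {
    d_lon <- with_stream(seed, 11L,
                         runif(n_districts, min(weather$lon),
                               max(weather$lon)))
    d_lat <- with_stream(seed, 12L,
                         runif(n_districts, min(weather$lat),
                               max(weather$lat)))
    district_ids <- sprintf("D%02d", seq_len(n_districts))
  } else {
    stopifnot(all(c("district_id", "lon", "lat") %in% names(districts)))
    n_districts <- nrow(districts)
    d_lon <- districts$lon; d_lat <- districts$lat
    district_ids <- as.character(districts$district_id)
  }

  district <- with_stream(seed, 13L, sample.int(n_districts, n, TRUE))
  survey_date <- with_stream(seed, 14L, sample(dates, n, TRUE))

  cov <- with_stream(seed, 15L, {
    age <- pmin(95, pmax(18, rnorm(n, 50, 12)))
    height <- pmin(2.0, pmax(1.4, rnorm(n, 1.62, 0.08)))
    bmi <- pmin(40, pmax(15, rnorm(n, 23, 3.2)))
    cbind(age = age, height = height, bmi = bmi)
  })
  cats <- with_stream(seed, 16L, .draw_categoricals(n))
  activity <- with_stream(seed, 17L, round(rexp(n, rate = 5), 1))
  sedentary <- with_stream(seed, 18L, round(rgamma(n, shape = 4, scale = 1), 1))

  groups <- names(truth$subgroup_mix)
  subgroup <- with_stream(
    seed, 19L, sample(groups, n, TRUE, prob = truth$subgroup_mix))

  xi <- with_stream(seed, 20L, rnorm(n_districts, 0, truth$district_sd))

  # exposure truth: IDW daily mean temperature at the district centroid
  if (is.null(series)) {
    districts_df <- data.frame(district_id = district_ids,
                               lon = d_lon, lat = d_lat)
    need_dates <- sort(unique(survey_date))
    series <- district_exposure_series(weather, districts_df,
                                       dates = need_dates,
                                       power = idw_power, vars = "tmean")
  }
  key <- paste(district_ids[district], survey_date)
  tsurvey <- series$tmean[match(key, paste(series$district_id, series$date))]
  if (anyNA(tsurvey)) {
    stop_thermoglyc("survey dates outside weather range",
                    "thermoglyc_generation_error")
  }

  eff <- truth$covariate_effects
  temp_effect <- vapply(seq_len(n), function(i) {
    polyval(truth$curve_params[[subgroup[i]]], tsurvey[i])
  }, numeric(1))
  mu <- truth$baseline_fpg[subgroup] + temp_effect +
    (eff$age %||% 0) * (cov[, "age"] - 50) +
    (eff$bmi %||% 0) * (cov[, "bmi"] - 23) +
    (eff$sex_male %||% 0) * (cats$sex == "male") +
    xi[district]

  eps <- with_stream(seed, 21L, {
    e <- rnorm(n, 0, truth$resid_sd)
    if (enforce_threshold && truth$resid_sd > 0) {
      # rejection-sample residuals so labels obey the 7.0 mmol/L rule
      for (iter in 1:200) {
        bad <- (subgroup == "NFG" & mu + e >= 7) |
          (subgroup == "NEWLY_DETECTED" & mu + e < 7)
        if (!any(bad)) break
        e[bad] <- rnorm(sum(bad), 0, truth$resid_sd)
      }
      bad <- (subgroup == "NFG" & mu + e >= 7) |
        (subgroup == "NEWLY_DETECTED" & mu + e < 7)
      if (any(bad)) {
        # deterministic fallback for means stranded far across the threshold
        e[bad] <- ifelse(subgroup[bad] == "NFG",
                         6.9 - mu[bad], 7.1 - mu[bad])
      }
    }
    e
  })
  fpg1 <- pmax(0.5, mu + eps)

  diagnosed <- subgroup == "KNOWN"
  med <- with_stream(seed, 22L, diagnosed & runif(n) < med_use_rate)

  data.frame(
    participant_id = sprintf("P%06d", seq_len(n)),
    district_id = district_ids[district],
    district_lon = d_lon[district], district_lat = d_lat[district],
    survey_date = survey_date,
    fpg1 = fpg1,
    diagnosed_t2dm = diagnosed, hypoglycemic_med = med,
    age = cov[, "age"], sex = cats$sex,
    height = cov[, "height"],
    weight = cov[, "bmi"] * cov[, "height"]^2,
    bmi = cov[, "bmi"],
    education = cats$education, career = cats$career,
    smoking = cats$smoking, drinking = cats$drinking,
    physical_activity = activity, sedentary_time = sedentary,
    truth_subgroup = subgroup,
    truth_tsurvey = tsurvey,
    truth_temp_effect = temp_effect,
    truth_district_effect = xi[district],
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Serialize / restore a truth spec
#'
#' Ground truth is written as a YAML key-value file so that validation
#' studies can reload exactly the generative parameters a cohort was built
#' from.
#'
#' @param truth a [truth_spec()].
#' @param path file path.
#' @return `write_truth_spec()` returns `path` invisibly;
#'   `read_truth_spec()` returns a `truth_spec`.
#' @export
write_truth_spec <- function(truth, path) {
  stopifnot(inherits(truth, "truth_spec"))
  x <- unclass(truth)
  x$subgroup_mix <- as.list(x$subgroup_mix)
  x$baseline_fpg <- as.list(x$baseline_fpg)
  yaml::write_yaml(x, path, precision = 12)
  invisible(path)
}

#' @rdname write_truth_spec
#' @export
read_truth_spec <- function(path) {
  x <- yaml::read_yaml(path)
  truth_spec(subgroup_mix = unlist(x$subgroup_mix),
             curve_params = lapply(x$curve_params, as.numeric),
             baseline_fpg = unlist(x$baseline_fpg),
             covariate_effects = x$covariate_effects,
             district_sd = x$district_sd, resid_sd = x$resid_sd,
             temp_range = as.numeric(x$temp_range), seed = x$seed)
}

#' Write station or cohort tables as CSV
#'
#' Plain UTF-8 CSV with a header row and ISO-8601 dates.
#'
#' @param x data.frame from [gen_station_weather()] or [gen_cohort()].
#' @param path output file.
#' @export
write_table_csv <- function(x, path) {
  write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_table_csv
#' @param date_cols columns to parse as `Date`.
#' @export
read_table_csv <- function(path, date_cols = c("date", "survey_date")) {
  x <- read.csv(path, stringsAsFactors = FALSE)
  for (col in intersect(date_cols, names(x))) x[[col]] <- as.Date(x[[col]])
  x
}
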