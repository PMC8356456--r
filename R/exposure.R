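# Exposure surface: inverse-distance-weighted interpolation of daily
# station meteorology to residential districts, k-fold cross-validation of
# the interpolator, and lag 0-6 exposure assignment.

.MET_VARS <- c("tmean", "tmin", "tmax", "humidity", "sunlight",
               "precipitation")

# great-circle distance in km between a target point and station coordinates
haversine_km <- function(lon, lat, s_lon, s_lat) {
  geosphere::distHaversine(c(lon, lat), cbind(s_lon, s_lat)) / 1000
}

#' Inverse-distance-weighted interpolation at a point
#'
#' Predicts meteorological values at a lon/lat target from one day's station
#' records. Weights are proportional to great-circle distance to the power
#' `-power` and are normalized to sum to 1, so every prediction is a convex
#' combination of station values (hence lies within the day's station range).
#' A target closer than `eps_km` to a station returns that station's value
#' exactly, making the interpolator exact at station locations.
#'
#' @param stations data.frame of station records for a single day (columns
#'   `lon`, `lat` and the variables in `vars`).
#' @param lon,lat target coordinates, degrees.
#' @param power positive IDW power (default 2).
#' @param vars variables to interpolate.
#' @param eps_km coincidence tolerance, km (default 1 m).
#' @return named numeric vector, one value per variable.
#' @export
idw_interpolate <- function(stations, lon, lat, power = 2,
                            vars = intersect(.MET_VARS, names(stations)),
                            eps_km = 0.001) {
  stopifnot(power > 0, nrow(stations) >= 1)
  d <- haversine_km(lon, lat, stations$lon, stations$lat)
  out <- setNames(numeric(length(vars)), vars)
  hit <- which(d < eps_km)
  for (v in vars) {
    vals <- stations[[v]]
    ok <- !is.na(vals)
    if (!any(ok)) {
      stop_thermoglyc(
        sprintf("no station data for '%s' on %s", v,
                format(stations$date[1] %||% NA)),
        "thermoglyc_missing_exposure", variable = v,
        date = stations$date[1] %||% NA)
    }
    hit_ok <- hit[ok[hit]]
    if (length(hit_ok)) {
      out[[v]] <- vals[hit_ok[1]]
    } else {
      w <- d[ok]^(-power)
      w <- w / sum(w)
      out[[v]] <- sum(w * vals[ok])
    }
  }
  out
}

#' Interpolate daily exposure series at district centroids
#'
#' Applies [idw_interpolate()] to every district for every date, producing
#' the per-district exposure series that lagged exposures are read from.
#'
#' @param stations station records ([gen_station_weather()] layout).
#' @param districts data.frame with `district_id`, `lon`, `lat`.
#' @param dates dates to interpolate (default: all dates in `stations`).
#' @param power IDW power.
#' @param vars variables to interpolate.
#' @return data.frame with `district_id`, `date` and one column per variable.
#' @export
district_exposure_series <- function(stations, districts, dates = NULL,
                                     power = 2,
                                     vars = intersect(.MET_VARS,
                                                      names(stations))) {
  stopifnot(all(c("district_id", "lon", "lat") %in% names(districts)))
  dates <- as.Date(dates %||% sort(unique(stations$date)))
  by_date <- split(stations, stations$date)
  rows <- vector("list", length(dates) * nrow(districts))
  i <- 0L
  for (day in as.character(dates)) {
    day_slice <- by_date[[day]]
    if (is.null(day_slice)) {
      stop_thermoglyc(sprintf("no station records on %s", day),
                      "thermoglyc_missing_exposure", date = day)
    }
    for (j in seq_len(nrow(districts))) {
      i <- i + 1L
      vals <- idw_interpolate(day_slice, districts$lon[j], districts$lat[j],
                              power = power, vars = vars)
      rows[[i]] <- c(list(district_id = districts$district_id[j],
                          date = day), as.list(vals))
    }
  }
  out <- do.call(rbind, lapply(rows, as.data.frame))
  out$date <- as.Date(out$date)
  out
}

#' Cross-validate the spatial interpolator
#'
#' Stations (not station-days) are partitioned into `k` folds; every
#' station-day of a held-out station is predicted by IDW from the remaining
#' stations on the same day, and accuracy is summarized per variable over
#' all held-out pairs. R^2 is the squared Pearson correlation between
#' observed and predicted values; it is `NA` when either side has zero
#' variance (e.g. a spatially constant field, for which RMSE is 0).
#'
#' @param stations station records.
#' @param k number of folds (>= 2; use `k` = number of stations for
#'   leave-one-out).
#' @param power IDW power.
#' @param seed integer seed controlling the fold assignment.
#' @param vars variables to validate.
#' @return data.frame (one row per variable) with `variable`, `r2`, `rmse`,
#'   `k`, `n_pred`, `seed`.
#' @export
crossvalidate_interpolation <- function(stations, k = 10, power = 2,
                                        seed = 1L,
                                        vars = intersect(.MET_VARS,
                                                         names(stations))) {
  ids <- unique(stations$station_id)
  if (k < 2 || length(ids) < k) {
    stop_thermoglyc("need at least k stations and k >= 2",
                    "thermoglyc_config_error")
  }
  fold <- with_stream(seed, 31L,
                      sample(rep_len(seq_len(k), length(ids))))
  names(fold) <- ids

  obs <- pred <- setNames(vector("list", length(vars)), vars)
  by_date <- split(stations, stations$date)
  for (day_slice in by_date) {
    f_day <- fold[day_slice$station_id]
    for (fi in unique(f_day)) {
      held <- day_slice[f_day == fi, , drop = FALSE]
      rest <- day_slice[f_day != fi, , drop = FALSE]
      if (nrow(rest) == 0) next
      for (r in seq_len(nrow(held))) {
        vals <- idw_interpolate(rest, held$lon[r], held$lat[r],
                                power = power, vars = vars)
        for (v in vars) {
          if (!is.na(held[[v]][r])) {
            obs[[v]] <- c(obs[[v]], held[[v]][r])
            pred[[v]] <- c(pred[[v]], vals[[v]])
          }
        }
      }
    }
  }
  res <- lapply(vars, function(v) {
    o <- obs[[v]]; p <- pred[[v]]
    r2 <- if (length(o) > 1 && sd(o) > 0 && sd(p) > 0) {
      stats::cor(o, p)^2
    } else NA_real_
    data.frame(variable = v, r2 = r2,
               rmse = sqrt(mean((o - p)^2)),
               k = k, n_pred = length(o), seed = seed,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Attach lagged exposures to a cohort
#'
#' For each participant, lag `l` exposure is the single-day interpolated
#' value `l` calendar days before the survey date (lag 0 = the survey day);
#' no moving averages are formed. Columns `<var>_lag<l>` are added for every
#' variable in the series and every lag `0..max_lag`.
#'
#' @param cohort participant data.frame with `district_id`, `survey_date`.
#' @param series district exposure series from [district_exposure_series()].
#' @param max_lag largest lag in days (default 6).
#' @param vars variables to attach (default: all series variables).
#' @return `cohort` with added exposure columns.
#' @export
assign_exposures <- function(cohort, series, max_lag = 6,
                             vars = setdiff(names(series),
                                            c("district_id", "date"))) {
  key <- paste(series$district_id, series$date)
  for (lag in 0:max_lag) {
    want <- paste(cohort$district_id, cohort$survey_date - lag)
    idx <- match(want, key)
    if (anyNA(idx)) {
      miss <- which(is.na(idx))[1]
      stop_thermoglyc(
        sprintf("no exposure series for participant %s district %s at lag %d (%s)",
                cohort$participant_id[miss] %||% miss,
                cohort$district_id[miss], lag,
                format(cohort$survey_date[miss] - lag)),
        "thermoglyc_missing_exposure")
    }
    for (v in vars) cohort[[paste0(v, "_lag", lag)]] <- series[[v]][idx]
  }
  cohort
}
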