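# Shared fixtures: tiny hand-placed station sets, toy curves and cohorts.
# All fixtures are built in code; nothing is read from disk.

# five hand-placed stations on a small lattice, `ndays` days of records
tiny_stations <- function(ndays = 1, values = c(17.3, 12.0, 20.0, 15.5, 9.8)) {
  lon <- c(113.0, 113.5, 112.5, 113.0, 113.0)
  lat <- c(23.0, 23.0, 23.0, 23.5, 22.5)
  out <- list()
  for (d in seq_len(ndays)) {
    out[[d]] <- data.frame(
      station_id = sprintf("S%02d", 1:5), lon = lon, lat = lat,
      date = as.Date("2014-01-01") + (d - 1),
      tmean = values + (d - 1) * 0.5,
      tmin = values - 3, tmax = values + 3,
      humidity = c(70, 75, 80, 72, 68), sunlight = 5, precipitation = 0,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

# brute-force IDW prediction used as the independent oracle: explicit loop,
# no shared code with idw_interpolate()
brute_idw <- function(stations, lon, lat, var = "tmean", power = 2) {
  num <- 0; den <- 0
  for (r in seq_len(nrow(stations))) {
    d_km <- geosphere::distHaversine(c(lon, lat),
                                     c(stations$lon[r], stations$lat[r])) / 1000
    if (d_km < 0.001) return(stations[[var]][r])
    w <- d_km^(-power)
    num <- num + w * stations[[var]][r]
    den <- den + w
  }
  num / den
}

# anchored fpg_curve fixture from an explicit function of temperature
toy_curve <- function(f, from = 5, to = 30, by = 0.1, subgroup = "KNOWN") {
  grid <- seq(from, to, by = by)
  val <- f(grid)
  anchor <- grid[max(which(val <= min(val) + 1e-12))]
  delta <- val - val[grid == anchor][1]
  structure(data.frame(temp = grid, delta = delta,
                       lo = delta, hi = delta),
            anchor = anchor, subgroup = subgroup,
            class = c("fpg_curve", "data.frame"))
}

flat_curve <- function(...) toy_curve(function(t) 0 * t, ...)

# minimal classified cohort for adjustment tests
toy_cohort <- function(fpg, subgroup, t_obs,
                       district = "D01",
                       date = as.Date("2014-01-15")) {
  data.frame(
    participant_id = sprintf("P%03d", seq_along(fpg)),
    district_id = district, survey_date = date,
    fpg1 = fpg,
    subgroup = factor(subgroup,
                      levels = c("NFG", "KNOWN", "NEWLY_DETECTED")),
    tmean_lag0 = t_obs, stringsAsFactors = FALSE)
}

# cohort drawn directly from an additive model (no weather machinery);
# used for model-level simulations where exposure truth is irrelevant
sim_model_cohort <- function(n, f_by_group, seed, resid_sd = 0.8,
                             n_districts = 12, district_sd = 0.15,
                             mix = NULL) {
  set.seed(seed)
  groups <- names(f_by_group)
  mix <- mix %||% rep(1 / length(groups), length(groups))
  subgroup <- sample(groups, n, TRUE, prob = mix)
  t <- runif(n, 5, 30)
  age <- rnorm(n, 50, 12); bmi <- rnorm(n, 23, 3)
  sex <- sample(c("male", "female"), n, TRUE)
  district <- sample(sprintf("D%02d", seq_len(n_districts)), n, TRUE)
  xi <- rnorm(n_districts, 0, district_sd)
  names(xi) <- sprintf("D%02d", seq_len(n_districts))
  fpg <- vapply(seq_len(n), function(i) f_by_group[[subgroup[i]]](t[i]),
                numeric(1)) +
    0.008 * (age - 50) + 0.02 * (bmi - 23) + 0.05 * (sex == "male") +
    xi[district] + rnorm(n, 0, resid_sd)
  data.frame(
    participant_id = seq_len(n), district_id = district,
    survey_date = as.Date("2014-01-01"), fpg1 = fpg,
    subgroup = factor(subgroup,
                      levels = c("NFG", "KNOWN", "NEWLY_DETECTED")),
    tmean_lag0 = t, humidity_lag0 = runif(n, 50, 95),
    age = age, bmi = bmi, sex = sex, stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
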