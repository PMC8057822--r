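# Independent oracles used across the suite. These deliberately share no
# code with the package implementation: plain loops and textbook formulas.

# 6mDM8h by brute force: every 8-h window mean, daily maxima, 6-month
# candidate means of daily values, maximum candidate.
oracle_6mdm8h <- function(x, time, wrap = TRUE) {
  nt <- length(x)
  wmean <- vapply(seq_len(nt - 7L), function(h) mean(x[h:(h + 7L)]),
                  numeric(1))
  date <- as.Date(format(time, "%Y-%m-%d", tz = "UTC"))
  days <- unique(date)
  start_date <- date[seq_len(nt - 7L)]
  dm <- vapply(days, function(d) max(wmean[start_date == d]), numeric(1))
  mon <- as.integer(format(days, "%m"))
  starts <- if (wrap) 1:12 else 1:7
  cands <- vapply(starts, function(s) {
    ms <- ((s - 1L):(s + 4L)) %% 12L + 1L
    mean(dm[mon %in% ms])
  }, numeric(1))
  max(cands)
}

# Even-odd ray casting over NA-separated rings (lon, lat columns).
oracle_point_in_poly <- function(px, py, rings) {
  splits <- which(is.na(rings[, 1]))
  bounds <- c(0, splits, nrow(rings) + 1L)
  inside <- FALSE
  for (k in seq_len(length(bounds) - 1L)) {
    ring <- rings[(bounds[k] + 1L):(bounds[k + 1L] - 1L), , drop = FALSE]
    n <- nrow(ring)
    j <- n
    for (i in seq_len(n)) {
      xi <- ring[i, 1]; yi <- ring[i, 2]
      xj <- ring[j, 1]; yj <- ring[j, 2]
      if ((yi > py) != (yj > py) &&
          px < (xj - xi) * (py - yi) / (yj - yi) + xi)
        inside <- !inside
      j <- i
    }
  }
  inside
}

# Great-circle distance (haversine, km) written out longhand.
oracle_gc_km <- function(lat1, lon1, lat2, lon2) {
  r <- 6378.137
  p <- pi / 180
  a <- sin((lat2 - lat1) * p / 2)^2 +
    cos(lat1 * p) * cos(lat2 * p) * sin((lon2 - lon1) * p / 2)^2
  2 * r * asin(pmin(1, sqrt(a)))
}

# Small reusable worlds -------------------------------------------------

config_with <- function(defaults, overrides) {
  do.call(synth_config, utils::modifyList(defaults, overrides))
}

tiny_config <- function(seed = 11, ...) {
  config_with(list(seed = seed, n_lat = 4L, n_lon = 6L, n_urban = 3L,
                   n_stations = 5L, total_population = 1e7),
              list(...))
}

# quiet generator config: no cycles, no noise, no obs corruption
flat_config <- function(seed = 11, ...) {
  config_with(list(
    seed = seed, n_lat = 4L, n_lon = 6L, n_urban = 3L, n_stations = 5L,
    total_population = 1e7,
    pm25 = list(background = 12, excess_pw = 55, diurnal_amp = 0,
                seasonal_amp = 0, noise_sd = 0, noise_rho = 0.9),
    o3 = list(background = 40, excess_pw = 25, diurnal_amp = 0,
              seasonal_amp = 0, noise_sd = 0, noise_rho = 0.9),
    obs_bias = 0, obs_noise_sd = 0, obs_missing_frac = 0),
    list(...))
}

# uniform exposure field helper
uniform_exposure <- function(value, grid, pollutant = "pm25",
                             scenario_id = "control") {
  metric <- if (pollutant == "pm25") "annual_mean_pm25" else "six_m_dm8h_o3"
  exposure_field(grid, pollutant, metric,
                 matrix(value, grid$n_lat, grid$n_lon), scenario_id)
}

# single-bracket age structure (all adult population in one bracket)
one_bracket_ages <- function(bracket = "60-64", frac = 1) {
  mid <- ifelse(age_brackets() == bracket, frac, 0)
  age_structure(data.frame(bracket = age_brackets(),
                           lower = mid, mid = mid, upper = mid))
}

# constant rates across brackets for one cause
flat_rates <- function(cause = "NCD_LRI", mort = 2000, yll = 30000,
                       yld = 5000, spread = 0) {
  df <- expand.grid(cause = cause, bracket = age_brackets(),
                    metric = c("MORT", "YLL", "YLD"),
                    stringsAsFactors = FALSE)
  df$mid <- c(MORT = mort, YLL = yll, YLD = yld)[df$metric]
  df$lower <- df$mid * (1 - spread)
  df$upper <- df$mid * (1 + spread)
  baseline_rates(df)
}
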