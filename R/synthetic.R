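#' Synthetic-world configuration
#'
#' Parameters of the seeded generator that stands in for chemical-transport
#' model output and the population/health input data. Defaults describe a
#' China-like desk-scale domain: a 24 x 36 one-degree grid, an urban-
#' concentrated population of 1.39 billion, GBD-like age structure and
#' baseline rates, sector-attributed concentration components with diurnal
#' and seasonal cycles, four policy-scenario archetypes, and a small
#' "GBA-like" focal region for inside/outside-domain scenario logic.
#'
#' @param seed Integer master seed; every generator output is a pure
#'   function of the configuration including this seed.
#' @param n_lat,n_lon Grid size (1-degree cells).
#' @param lat0,lon0 South-west corner (cell edge) of the domain.
#' @param year Simulated calendar year.
#' @param total_population Total persons in the domain.
#' @param urban_share Fraction of population in Gaussian urban peaks.
#' @param n_urban Number of urban centers.
#' @param pm25,o3 Per-pollutant lists: `background` (regional baseline),
#'   `excess_pw` (target population-weighted mean of the summed sector
#'   components), `diurnal_amp`, `seasonal_amp`, `noise_sd`, `noise_rho`
#'   (hourly AR(1) autocorrelation).
#' @param sector_shares Per-pollutant named shares of the excess
#'   concentration attributed to `residential`, `industry`, `transport`,
#'   `agriculture` (an NH3 proxy) and `other`; each set sums to 1.
#' @param voc_limited_frac Fraction of cells (the most urban ones) treated
#'   as VOC-limited, where precursor cuts with `o3_mode = "regime"` raise
#'   ozone.
#' @param scenarios Named list of scenario definitions: `sector`,
#'   `scaling` in `[0, 1]`, `domain` (`"all"`, `"outside_gba"`,
#'   `"inside_gba"`) and `o3_mode` (`"monotonic"` or `"regime"`).
#' @param n_stations,obs_bias,obs_noise_sd,obs_missing_frac Monitoring
#'   network emulation: station count, multiplicative observation bias,
#'   additive noise standard deviation, and missingness fraction.
#' @param gba `c(lat0, lat1, lon0, lon1)` box of the focal region.
#' @return Validated list of class `ab_synth_config`.
#' @export
synth_config <- function(
    seed = 1L,
    n_lat = 24L, n_lon = 36L, lat0 = 18, lon0 = 98,
    year = 2015,
    total_population = 1.39e9, urban_share = 0.62, n_urban = 18L,
    pm25 = list(background = 12, excess_pw = 55, diurnal_amp = 0.25,
                seasonal_amp = 0.40, noise_sd = 8, noise_rho = 0.9),
    o3 = list(background = 40, excess_pw = 25, diurnal_amp = 0.45,
              seasonal_amp = 0.30, noise_sd = 6, noise_rho = 0.9),
    sector_shares = list(
      pm25 = c(residential = 0.35, industry = 0.25, transport = 0.06,
               agriculture = 0.18, other = 0.16),
      o3 = c(residential = 0.15, industry = 0.30, transport = 0.35,
             agriculture = 0.10, other = 0.10)),
    voc_limited_frac = 0.35,
    scenarios = list(
      RES = list(sector = "residential", scaling = 0.5,
                 domain = "outside_gba", o3_mode = "monotonic"),
      AGR = list(sector = "agriculture", scaling = 0.3,
                 domain = "outside_gba", o3_mode = "regime"),
      TRA = list(sector = "transport", scaling = 0.8,
                 domain = "all", o3_mode = "regime"),
      IND = list(sector = "industry", scaling = 0.1,
                 domain = "all", o3_mode = "monotonic")),
    n_stations = 40L, obs_bias = 0.1, obs_noise_sd = 5,
    obs_missing_frac = 0.02,
    gba = c(21.5, 24.5, 111.5, 115.5)) {
  cfg <- list(seed = as.integer(seed), n_lat = n_lat, n_lon = n_lon,
              lat0 = lat0, lon0 = lon0, year = year,
              total_population = total_population,
              urban_share = urban_share, n_urban = n_urban,
              pm25 = pm25, o3 = o3, sector_shares = sector_shares,
              voc_limited_frac = voc_limited_frac, scenarios = scenarios,
              n_stations = n_stations, obs_bias = obs_bias,
              obs_noise_sd = obs_noise_sd,
              obs_missing_frac = obs_missing_frac, gba = gba)
  for (p in c("pm25", "o3")) {
    sh <- cfg$sector_shares[[p]]
    if (any(sh < 0) || abs(sum(sh) - 1) > 1e-9)
      stop(sprintf("validation error: %s sector shares must be >= 0 and sum to 1", p),
           call. = FALSE)
  }
  if (cfg$urban_share < 0 || cfg$urban_share > 1)
    stop("validation error: urban share must lie in [0, 1]", call. = FALSE)
  for (s in names(cfg$scenarios)) {
    sc <- cfg$scenarios[[s]]
    if (sc$scaling < 0 || sc$scaling > 1)
      stop(sprintf("validation error: scenario '%s' scaling must lie in [0, 1]", s),
           call. = FALSE)
  }
  class(cfg) <- "ab_synth_config"
  cfg
}

synth_grid <- function(config) {
  ab_grid(lat = config$lat0 + seq_len(config$n_lat) - 0.5,
          lon = config$lon0 + seq_len(config$n_lon) - 0.5)
}

# default GBD-like tables -------------------------------------------------

synth_age_structure <- function() {
  mid <- c(0.081, 0.075, 0.069, 0.082, 0.081, 0.070, 0.050, 0.043,
           0.032, 0.022, 0.015, 0.015)
  age_structure(data.frame(bracket = age_brackets(),
                           lower = mid * 0.97, mid = mid,
                           upper = mid * 1.03))
}

synth_baseline_rates <- function() {
  br <- age_brackets()
  mort_ncd <- c(80, 100, 140, 200, 300, 450, 700, 1100, 1800, 3000,
                5200, 13000)
  mort_copd <- c(1, 1.5, 2, 4, 8, 15, 30, 60, 120, 250, 480, 1000)
  yll_mult <- c(50, 45, 40, 36, 32, 28, 24, 20, 16, 12, 9, 7)
  mk <- function(cause, mort, yld_frac) {
    do.call(rbind, list(
      data.frame(cause = cause, bracket = br, metric = "MORT", mid = mort),
      data.frame(cause = cause, bracket = br, metric = "YLL",
                 mid = mort * yll_mult),
      data.frame(cause = cause, bracket = br, metric = "YLD",
                 mid = mort * yll_mult * yld_frac)))
  }
  df <- rbind(mk("NCD_LRI", mort_ncd, 0.25), mk("COPD", mort_copd, 0.5))
  df$lower <- df$mid * 0.9
  df$upper <- df$mid * 1.1
  baseline_rates(df)
}

synth_region_boxes <- function(config) {
  lat1 <- config$lat0 + config$n_lat
  lon1 <- config$lon0 + config$n_lon
  lat_mid <- config$lat0 + round(config$n_lat / 2)
  lon_a <- config$lon0 + round(config$n_lon / 3)
  lon_b <- config$lon0 + round(2 * config$n_lon / 3)
  list(
    north_west = c(lat_mid, lat1, config$lon0, lon_a),
    north = c(lat_mid, lat1, lon_a, lon_b),
    north_east = c(lat_mid, lat1, lon_b, lon1),
    south_west = c(config$lat0, lat_mid, config$lon0, lon_a),
    south_central = c(config$lat0, lat_mid, lon_a, lon_b),
    east = c(config$lat0, lat_mid, lon_b, lon1))
}

box_weights <- function(box, grid) {
  inside_lat <- grid$lat > box[1] & grid$lat < box[2]
  inside_lon <- grid$lon > box[3] & grid$lon < box[4]
  outer(inside_lat, inside_lon) * 1.0
}

#' Generate the synthetic world
#'
#' Builds the static inputs: grid, population (smooth rural field plus
#' Gaussian urban peaks, normalized to the configured total), age-structure
#' table, baseline-rate table, a 6-region partition of the domain, and the
#' focal "GBA-like" region mask.
#'
#' @param config An [synth_config()].
#' @return List of class `ab_world`: `grid`, `pop`, `ages`, `rates`,
#'   `masks` (the partition), `gba_mask`, `geometries` (rings for GeoJSON
#'   export), `urban_centers`, `urban_field` (the urban population share
#'   per cell).
#' @export
gen_world <- function(config) {
  grid <- synth_grid(config)
  set.seed(config$seed + 1L)
  # smooth rural surface: gentle large-scale waves plus an eastward gradient
  lat_n <- (grid$lat - min(grid$lat)) / max(1e-9, diff(range(grid$lat)))
  lon_n <- (grid$lon - min(grid$lon)) / max(1e-9, diff(range(grid$lon)))
  rural <- outer(1 + 0.4 * sin(pi * lat_n), 0.3 + 0.7 * lon_n) +
    0.3 * outer(cos(2 * pi * lat_n), sin(2 * pi * lon_n))
  rural <- pmax(rural, 0.05)
  # urban peaks, placed preferentially where the rural field is dense
  urban <- matrix(0, grid$n_lat, grid$n_lon)
  centers <- NULL
  if (config$urban_share > 0 && config$n_urban > 0) {
    prob <- rural / sum(rural)
    idx <- sample.int(grid$n_lat * grid$n_lon, config$n_urban,
                      replace = FALSE, prob = as.vector(prob))
    ij <- arrayInd(idx, dim(rural))
    amp <- stats::rlnorm(config$n_urban, 0, 0.6)
    sdc <- stats::runif(config$n_urban, 0.8, 1.6)  # in cells
    rows <- matrix(seq_len(grid$n_lat), grid$n_lat, grid$n_lon)
    cols <- matrix(seq_len(grid$n_lon), grid$n_lat, grid$n_lon, byrow = TRUE)
    for (k in seq_len(config$n_urban)) {
      d2 <- (rows - ij[k, 1])^2 + (cols - ij[k, 2])^2
      urban <- urban + amp[k] * exp(-d2 / (2 * sdc[k]^2))
    }
    centers <- data.frame(lat = grid$lat[ij[, 1]], lon = grid$lon[ij[, 2]],
                          amp = amp, sd_cells = sdc)
  }
  counts <- rural / sum(rural) * config$total_population *
    (1 - config$urban_share)
  if (sum(urban) > 0)
    counts <- counts + urban / sum(urban) * config$total_population *
      config$urban_share
  pop <- pop_grid(grid, counts)

  boxes <- synth_region_boxes(config)
  masks <- lapply_named(boxes, function(id, b)
    region_mask(id, box_weights(b, grid), grid))
  gba_mask <- region_mask("gba", box_weights(config$gba, grid), grid)
  geometries <- c(lapply(boxes, function(b)
    rect_ring(b[1], b[2], b[3], b[4])),
    list(gba = rect_ring(config$gba[1], config$gba[2],
                         config$gba[3], config$gba[4])))
  structure(list(grid = grid, pop = pop, ages = synth_age_structure(),
                 rates = synth_baseline_rates(), masks = masks,
                 gba_mask = gba_mask, geometries = geometries,
                 urban_centers = centers,
                 urban_field = if (sum(urban) > 0) urban / sum(urban)
                               else urban),
            class = "ab_world")
}

# sector spatial patterns (unnormalized)
sector_pattern <- function(sector, world) {
  popn <- world$pop$counts / sum(world$pop$counts)
  urb <- world$urban_field
  switch(sector,
    residential = popn^0.8,
    industry = 0.2 * popn + (if (sum(urb) > 0) urb else popn),
    transport = popn,
    agriculture = pmax(popn * 0.2, max(popn) * 0.05) +
      (max(popn) - popn) * 0.1,
    other = matrix(1, world$grid$n_lat, world$grid$n_lon),
    stop(sprintf("configuration error: unknown sector '%s'", sector),
         call. = FALSE))
}

# temporal modulation: non-negative by construction (amplitudes < 1 summed)
sector_modulation <- function(sector, pollutant, cfg_p, time, year) {
  hour <- as.numeric(format(time, "%H", tz = "UTC"))
  doy <- as.numeric(format(time, "%j", tz = "UTC"))
  ndays <- 365 + (length(time) > 8760)
  diurnal_phase <- switch(sector, residential = 19, transport = 8,
                          industry = 12, agriculture = 6, other = 0)
  # PM2.5 peaks in winter (residential heating most strongly); O3 in summer
  seasonal_sign <- if (pollutant == "pm25") 1 else -1
  seas_amp <- cfg_p$seasonal_amp *
    switch(sector, residential = 1.3, agriculture = 0.8, 1)
  mod <- 1 +
    cfg_p$diurnal_amp * sin(2 * pi * (hour - diurnal_phase + 6) / 24) +
    seasonal_sign * seas_amp * cos(2 * pi * (doy - 15) / ndays)
  pmax(mod, 0)
}

ar1_noise <- function(n_cell, n_time, sd, rho) {
  innov <- matrix(stats::rnorm(n_cell * n_time, 0,
                               sd * sqrt(1 - rho^2)), n_time, n_cell)
  x <- stats::filter(innov, rho, method = "recursive")
  t(matrix(as.numeric(x), n_time, n_cell))
}

#' Generate control concentration fields
#'
#' Builds hourly control-run fields for both pollutants as
#' `background + sum over sectors of (spatial component x temporal
#' modulation) + AR(1) noise`, clipped at zero. The exact sector components
#' and the noise term are retained in the returned truth object so tests can
#' verify the bookkeeping identity and scenarios can be derived linearly.
#'
#' @param config An [synth_config()].
#' @param world An `ab_world` from [gen_world()].
#' @return List of class `ab_truth`: per pollutant a list with `background`,
#'   `maps` (cells x sectors spatial components), `mods` (hours x sectors
#'   modulations), `noise`, `preclip` (cells x hours, before clipping),
#'   `clip_count`, and `control` (the clipped [conc_field()]); plus the
#'   O3 `regime_sign` matrix (+1 NOx-limited, -1 VOC-limited) and the time
#'   axis.
#' @export
gen_concentrations <- function(config, world) {
  time <- year_hours(config$year)
  nt <- length(time)
  grid <- world$grid
  n_cell <- grid$n_lat * grid$n_lon
  out <- list(time = time, grid = grid)
  for (p in c("pm25", "o3")) {
    cfg_p <- config[[p]]
    shares <- config$sector_shares[[p]]
    sectors <- names(shares)
    maps <- matrix(0, n_cell, length(sectors),
                   dimnames = list(NULL, sectors))
    mods <- matrix(0, nt, length(sectors), dimnames = list(NULL, sectors))
    wpop <- as.vector(world$pop$counts)
    for (s in sectors) {
      raw <- as.vector(sector_pattern(s, world))
      pw <- sum(raw * wpop) / sum(wpop)
      maps[, s] <- raw / pw * shares[[s]] * cfg_p$excess_pw
      mods[, s] <- sector_modulation(s, p, cfg_p, time, config$year)
      # normalize modulation to annual mean 1 so annual-mean components
      # equal the spatial maps exactly
      mods[, s] <- mods[, s] / mean(mods[, s])
    }
    set.seed(config$seed + if (p == "pm25") 2L else 3L)
    noise <- if (cfg_p$noise_sd > 0)
      ar1_noise(n_cell, nt, cfg_p$noise_sd, cfg_p$noise_rho)
    else matrix(0, n_cell, nt)
    preclip <- cfg_p$background + maps %*% t(mods) + noise
    clip_count <- sum(preclip < 0)
    control <- conc_field(grid, p,
                          array(pmax(preclip, 0),
                                dim = c(grid$n_lat, grid$n_lon, nt)),
                          time = time, scenario_id = "control")
    out[[p]] <- list(background = cfg_p$background, maps = maps,
                     mods = mods, noise = noise, preclip = preclip,
                     clip_count = clip_count, control = control)
  }
  set.seed(config$seed + 5L)
  n_voc <- round(config$voc_limited_frac * n_cell)
  sign_map <- matrix(1, grid$n_lat, grid$n_lon)
  if (n_voc > 0) {
    ord <- order(as.vector(world$pop$counts), decreasing = TRUE)
    sign_map[ord[seq_len(n_voc)]] <- -1
  }
  out$regime_sign <- sign_map
  class(out) <- "ab_truth"
  out
}

scenario_domain_weights <- function(domain, world) {
  switch(domain,
    all = matrix(1, world$grid$n_lat, world$grid$n_lon),
    outside_gba = 1 - world$gba_mask$weights,
    inside_gba = world$gba_mask$weights,
    stop(sprintf("configuration error: unknown scenario domain '%s'", domain),
         call. = FALSE))
}

#' Derive a policy-scenario field from the synthetic truth
#'
#' Linear source surrogate: the scenario removes `scaling` times the named
#' sector's concentration component within the spatial domain. For PM2.5 the
#' response is a monotone decrease. For ozone with `o3_mode = "regime"` the
#' response is signed: concentrations fall in NOx-limited cells and rise in
#' the configured VOC-limited (urban) fraction, emulating the regime
#' dependence of ozone chemistry under precursor cuts.
#'
#' @param truth An `ab_truth` from [gen_concentrations()].
#' @param world The matching `ab_world`.
#' @param scenario One element of `config$scenarios` (list with `sector`,
#'   `scaling`, `domain`, `o3_mode`).
#' @param scenario_id Label for the derived fields.
#' @return List with hourly [conc_field()]s `pm25` and `o3`.
#' @export
gen_scenario <- function(truth, world, scenario, scenario_id = "scenario") {
  dom <- as.vector(scenario_domain_weights(scenario$domain, world))
  out <- list()
  for (p in c("pm25", "o3")) {
    tp <- truth[[p]]
    if (!scenario$sector %in% colnames(tp$maps))
      stop(sprintf("configuration error: unknown sector '%s'",
                   scenario$sector), call. = FALSE)
    dmap <- scenario$scaling * tp$maps[, scenario$sector] * dom
    if (p == "o3" && identical(scenario$o3_mode, "regime"))
      dmap <- dmap * as.vector(truth$regime_sign)
    preclip <- tp$preclip - outer(dmap, tp$mods[, scenario$sector])
    grid <- truth$grid
    out[[p]] <- conc_field(grid, p,
                           array(pmax(preclip, 0),
                                 dim = c(grid$n_lat, grid$n_lon,
                                         nrow(tp$mods))),
                           time = truth$time, scenario_id = scenario_id)
  }
  out
}

#' Generate noisy station observations
#'
#' Places stations in population-weighted random cells (uniform placement
#' optional), jitters their coordinates within the cell, and observes the
#' true cell series with a multiplicative bias, additive Gaussian noise and
#' random missingness.
#'
#' @param truth An `ab_truth`.
#' @param world The matching `ab_world`.
#' @param config The [synth_config()].
#' @param pollutant `"pm25"` or `"o3"`.
#' @param population_weighted Place stations preferentially in populated
#'   cells (default `TRUE`).
#' @param every Observe every `every`-th hour (default 1 = hourly).
#' @return An [stations()] table.
#' @export
gen_stations <- function(truth, world, config, pollutant = "pm25",
                         population_weighted = TRUE, every = 1L) {
  set.seed(config$seed + 4L)
  grid <- world$grid
  n_cell <- grid$n_lat * grid$n_lon
  prob <- if (population_weighted)
    as.vector(world$pop$counts) / sum(world$pop$counts)
  else rep(1 / n_cell, n_cell)
  n_st <- min(config$n_stations, n_cell)
  cells <- sample.int(n_cell, n_st, replace = FALSE, prob = prob)
  ij <- arrayInd(cells, c(grid$n_lat, grid$n_lon))
  jit <- function(n) stats::runif(n, -0.35, 0.35)
  lat_step <- if (grid$n_lat > 1) abs(grid$lat[2] - grid$lat[1]) else 1
  lon_step <- if (grid$n_lon > 1) abs(grid$lon[2] - grid$lon[1]) else 1
  lat_st <- grid$lat[ij[, 1]] + jit(n_st) * lat_step
  lon_st <- grid$lon[ij[, 2]] + jit(n_st) * lon_step
  tsel <- seq(1L, length(truth$time), by = every)
  truth_mat <- matrix(truth[[pollutant]]$control$values, nrow = n_cell)
  rows <- vector("list", n_st)
  for (k in seq_len(n_st)) {
    true_series <- truth_mat[cells[k], tsel]
    obs <- true_series * (1 + config$obs_bias)
    if (config$obs_noise_sd > 0)
      obs <- obs + stats::rnorm(length(obs), 0, config$obs_noise_sd)
    if (config$obs_missing_frac > 0)
      obs[stats::runif(length(obs)) < config$obs_missing_frac] <- NA_real_
    rows[[k]] <- data.frame(station_id = sprintf("st%03d", k),
                            lat = lat_st[k], lon = lon_st[k],
                            timestamp = truth$time[tsel], value = obs)
  }
  stations(do.call(rbind, rows))
}

#' Write the full synthetic input bundle to disk
#'
#' NetCDF concentration and population files, CSV age-structure, rate and
#' station tables, and GeoJSON region geometries -- the complete set of
#' pipeline inputs the generator emulates.
#'
#' @param config An [synth_config()].
#' @param dir Output directory (created if needed).
#' @param scenarios Generate and write scenario fields too (default `TRUE`).
#' @return Invisible named list of written paths.
#' @export
write_input_bundle <- function(config, dir, scenarios = TRUE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  world <- gen_world(config)
  truth <- gen_concentrations(config, world)
  paths <- list()
  p_at <- function(f) file.path(dir, f)
  for (p in c("pm25", "o3"))
    paths[[paste0(p, "_control")]] <-
      write_concentration_field(truth[[p]]$control,
                                p_at(sprintf("%s_control.nc", p)))
  if (scenarios) {
    for (s in names(config$scenarios)) {
      flds <- gen_scenario(truth, world, config$scenarios[[s]], s)
      for (p in c("pm25", "o3"))
        paths[[paste(p, s, sep = "_")]] <-
          write_concentration_field(flds[[p]],
                                    p_at(sprintf("%s_%s.nc", p, s)))
    }
  }
  paths$population <- write_population(world$pop, p_at("population.nc"))
  utils::write.csv(world$ages, p_at("age_structure.csv"), row.names = FALSE)
  utils::write.csv(world$rates, p_at("baseline_rates.csv"),
                   row.names = FALSE)
  paths$regions <- write_geojson_regions(world$geometries,
                                         p_at("regions.geojson"))
  st <- gen_stations(truth, world, config, "pm25")
  paths$stations <- write_stations(st, p_at("stations_pm25.csv"))
  paths$ages <- p_at("age_structure.csv")
  paths$rates <- p_at("baseline_rates.csv")
  invisible(paths)
}
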