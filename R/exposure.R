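#' Per-cell exposure field
#'
#' A scalar exposure per grid cell: the annual-mean PM2.5 concentration
#' (ug m-3) or the 6mDM8h ozone metric (ppb).
#'
#' @param grid An [ab_grid()].
#' @param pollutant `"pm25"` or `"o3"`.
#' @param metric `"annual_mean_pm25"` or `"six_m_dm8h_o3"`.
#' @param values `[lat, lon]` matrix, non-negative and finite.
#' @param scenario_id Run label.
#' @return An object of class `ab_exposure`.
#' @export
exposure_field <- function(grid, pollutant, metric, values,
                           scenario_id = "control") {
  pollutant <- match.arg(pollutant, c("pm25", "o3"))
  metric <- match.arg(metric, c("annual_mean_pm25", "six_m_dm8h_o3"))
  values <- as.matrix(values)
  if (!all(dim(values) == c(grid$n_lat, grid$n_lon)))
    stop("exposure values must be an [n_lat, n_lon] matrix", call. = FALSE)
  if (anyNA(values) || any(!is.finite(values)) || any(values < 0))
    stop("exposure values must be finite and non-negative", call. = FALSE)
  structure(list(grid = grid, pollutant = pollutant, metric = metric,
                 values = values, scenario_id = scenario_id),
            class = "ab_exposure")
}

#' @export
print.ab_exposure <- function(x, ...) {
  cat(sprintf("<ab_exposure> %s (%s), %d x %d cells, scenario '%s'\n",
              x$metric, conc_units(x$pollutant), x$grid$n_lat, x$grid$n_lon,
              x$scenario_id))
  invisible(x)
}

#' Annual-mean PM2.5 exposure
#'
#' Per-cell arithmetic mean over all time steps of an hourly (or daily)
#' PM2.5 field; annual fields pass through unchanged.
#'
#' @param field An [conc_field()] with `pollutant = "pm25"`.
#' @return An [exposure_field()] with metric `annual_mean_pm25`.
#' @export
annual_mean <- function(field) {
  if (field$pollutant != "pm25")
    stop("annual_mean is the PM2.5 exposure metric; use six_m_dm8h for O3",
         call. = FALSE)
  if (field$annual) {
    vals <- field$values
  } else {
    nt <- dim(field$values)[3]
    if (nt == 0L) stop("empty time axis", call. = FALSE)
    vals <- rowMeans(matrix(field$values,
                            nrow = field$grid$n_lat * field$grid$n_lon,
                            ncol = nt))
    vals <- matrix(vals, field$grid$n_lat, field$grid$n_lon)
  }
  exposure_field(field$grid, "pm25", "annual_mean_pm25", vals,
                 field$scenario_id)
}

#' 6-monthly mean daily maximum 8-hour ozone (6mDM8h)
#'
#' The ozone exposure metric: (i) for each start hour, the forward-looking
#' 8-hour mean (windows running past the end of the year are dropped);
#' (ii) each day's value is the maximum over the (up to) 24 window means
#' starting that day; (iii) candidate means of the daily values over 6
#' consecutive calendar months, starting at each of the 12 months and, by
#' default, wrapping within the same year; (iv) the metric is the maximum
#' candidate.
#'
#' @param field Hourly [conc_field()] with `pollutant = "o3"` covering one
#'   calendar year.
#' @param wrap If `TRUE` (default) all 12 six-month windows are used,
#'   wrapping within the year; if `FALSE` only the 7 non-wrapping windows
#'   (Jan-Jun ... Jul-Dec).
#' @return An [exposure_field()] with metric `six_m_dm8h_o3`.
#' @export
six_m_dm8h <- function(field, wrap = TRUE) {
  if (field$pollutant != "o3")
    stop("six_m_dm8h is defined for O3 fields", call. = FALSE)
  if (field$annual)
    stop("six_m_dm8h needs an hourly field covering one calendar year",
         call. = FALSE)
  tt <- field$time
  nt <- length(tt)
  yr <- as.integer(format(tt[1], "%Y", tz = "UTC"))
  ref <- year_hours(yr)
  if (nt != length(ref) || abs(as.numeric(tt[1]) - as.numeric(ref[1])) > 1e-6)
    stop("six_m_dm8h needs a complete hourly calendar year", call. = FALSE)
  n_cell <- field$grid$n_lat * field$grid$n_lon
  m <- matrix(field$values, nrow = n_cell, ncol = nt)  # cells x hours

  # (i) 8-h forward rolling means for start hours 1 .. nt-7
  cs <- apply(t(m), 2, cumsum)                         # hours x cells
  cs <- rbind(0, cs)
  n_win <- nt - 7L
  win <- (cs[(1:n_win) + 8L, , drop = FALSE] -
            cs[1:n_win, , drop = FALSE]) / 8           # windows x cells

  # (ii) daily maxima over window means starting within each day
  day_of <- rep(seq_len(nt / 24L), each = 24L)[1:n_win]
  n_day <- nt / 24L
  dm <- matrix(NA_real_, n_day, n_cell)
  for (d in seq_len(n_day)) {
    rows <- which(day_of == d)
    dm[d, ] <- apply(win[rows, , drop = FALSE], 2, max)
  }

  # (iii) 6-month candidate means of daily values (weighted by month length)
  month_of_day <- as.integer(format(
    as.Date(sprintf("%d-01-01", yr)) + seq_len(n_day) - 1L, "%m"))
  msum <- rowsum(dm, month_of_day)                     # 12 x cells
  mcnt <- tabulate(month_of_day, nbins = 12L)
  starts <- if (wrap) 1:12 else 1:7
  best <- rep(-Inf, n_cell)
  for (s in starts) {
    months <- ((s - 1L):(s + 4L)) %% 12L + 1L
    cand <- colSums(msum[months, , drop = FALSE]) / sum(mcnt[months])
    best <- pmax(best, cand)
  }
  exposure_field(field$grid, "o3", "six_m_dm8h_o3",
                 matrix(best, field$grid$n_lat, field$grid$n_lon),
                 field$scenario_id)
}

#' Population-weighted mean exposure
#'
#' `sum(value * P * w) / sum(P * w)` over cells, with `w` the region-mask
#' weight.
#'
#' @param exposure An [exposure_field()].
#' @param pop An [pop_grid()] on the same grid.
#' @param mask An optional [region_mask()]; default is the whole grid.
#' @return Scalar exposure (ug m-3 or ppb).
#' @export
population_weighted_mean <- function(exposure, pop, mask = NULL) {
  stopifnot_same_grid(exposure$grid, pop$grid)
  w <- if (is.null(mask)) 1 else {
    stopifnot_same_grid(exposure$grid, mask$grid)
    mask$weights
  }
  denom <- sum(pop$counts * w)
  if (denom <= 0)
    stop("undefined exposure: zero population weight in region", call. = FALSE)
  sum(exposure$values * pop$counts * w) / denom
}

#' Round half away from zero
#'
#' Commercial rounding used for reported percent changes (`round()` in R
#' rounds half to even).
#'
#' @param x Numeric.
#' @param digits Decimal digits (default 0).
#' @return Rounded numeric.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Population-weighted exposure change between scenarios
#'
#' Absolute change is `PW(control) - PW(scenario)` (positive when the
#' scenario lowers exposure); percent change is relative to the control and
#' reported rounded half-up to the nearest integer.
#'
#' @param control,scenario [exposure_field()]s sharing grid, pollutant and
#'   metric.
#' @param pop An [pop_grid()].
#' @param mask Optional [region_mask()].
#' @return List with `pw_control`, `pw_scenario`, `absolute`, `percent`
#'   (exact) and `percent_reported` (integer, half-up).
#' @export
scenario_delta <- function(control, scenario, pop, mask = NULL) {
  if (control$pollutant != scenario$pollutant ||
      control$metric != scenario$metric)
    stop("control and scenario must share pollutant and metric", call. = FALSE)
  stopifnot_same_grid(control$grid, scenario$grid)
  pc <- population_weighted_mean(control, pop, mask)
  ps <- population_weighted_mean(scenario, pop, mask)
  absolute <- pc - ps
  if (pc == 0)
    stop("undefined percent change: control exposure is zero", call. = FALSE)
  percent <- 100 * absolute / pc
  list(pw_control = pc, pw_scenario = ps, absolute = absolute,
       percent = percent, percent_reported = round_half_up(percent))
}

#' Bias-adjust a simulated exposure
#'
#' Applies the evaluated normalized mean bias factor to a simulated
#' exposure: `adjusted = exposure * (1 - NMBF)`. A positive NMBF
#' (overestimation) scales the exposure down; a negative NMBF scales it up.
#'
#' @param exposure Scalar exposure or [exposure_field()].
#' @param nmbf Normalized mean bias factor; must exceed -1.
#' @return Adjusted exposure, same shape as the input.
#' @examples
#' bias_adjust(39.6, 0.13)   # 34.452
#' bias_adjust(61.3, -0.25)  # 76.625
#' @export
bias_adjust <- function(exposure, nmbf) {
  if (!is.finite(nmbf) || nmbf <= -1)
    stop("nmbf must be a finite value greater than -1", call. = FALSE)
  if (inherits(exposure, "ab_exposure")) {
    exposure$values <- exposure$values * (1 - nmbf)
    exposure
  } else {
    exposure * (1 - nmbf)
  }
}
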