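#' Gridded pollutant concentration field
#'
#' Container for one scenario's concentrations of one pollutant. Hourly
#' fields carry a strictly increasing hourly `POSIXct` time axis covering one
#' calendar year; annual fields carry a single `[lat, lon]` matrix and
#' `annual = TRUE`. Units are canonical: ug m-3 for PM2.5, ppb for O3.
#'
#' @param grid An [ab_grid()].
#' @param pollutant `"pm25"` or `"o3"`.
#' @param values `[lat, lon, time]` array (hourly) or `[lat, lon]` matrix
#'   (annual).
#' @param time `POSIXct` (UTC) hourly axis, or `NULL` for annual fields.
#' @param scenario_id Label for the run, e.g. `"control"`.
#' @return An object of class `ab_conc_field`.
#' @export
conc_field <- function(grid, pollutant, values, time = NULL,
                       scenario_id = "control") {
  pollutant <- match.arg(pollutant, c("pm25", "o3"))
  annual <- is.null(time)
  if (annual) {
    values <- as.matrix(values)
    if (!all(dim(values) == c(grid$n_lat, grid$n_lon)))
      stop("annual values must be an [n_lat, n_lon] matrix", call. = FALSE)
  } else {
    if (length(dim(values)) != 3L ||
        !all(dim(values)[1:2] == c(grid$n_lat, grid$n_lon)) ||
        dim(values)[3] != length(time))
      stop("hourly values must be an [n_lat, n_lon, n_time] array matching the time axis",
           call. = FALSE)
    dt <- diff(as.numeric(time))
    if (length(dt) && (any(dt <= 0) || any(abs(dt - 3600) > 1e-6)))
      stop("time axis must be strictly increasing with a uniform 1-hour step",
           call. = FALSE)
  }
  if (anyNA(values) || any(!is.finite(values)))
    stop("concentration values must be finite", call. = FALSE)
  if (any(values < 0))
    stop("concentration values must be non-negative", call. = FALSE)
  structure(
    list(grid = grid, pollutant = pollutant, values = values, time = time,
         annual = annual, scenario_id = scenario_id),
    class = "ab_conc_field"
  )
}

#' @export
print.ab_conc_field <- function(x, ...) {
  cat(sprintf("<ab_conc_field> %s [%s], %d x %d cells, %s, scenario '%s'\n",
              toupper(x$pollutant), conc_units(x$pollutant),
              x$grid$n_lat, x$grid$n_lon,
              if (x$annual) "annual" else sprintf("%d hourly steps",
                                                 length(x$time)),
              x$scenario_id))
  invisible(x)
}

conc_units <- function(pollutant) {
  if (pollutant == "pm25") "ug m-3" else "ppb"
}

#' Hourly time axis for one calendar year
#'
#' @param year Calendar year (default 2015, a 365-day year).
#' @return `POSIXct` (UTC) vector of every hour of the year.
#' @export
year_hours <- function(year = 2015) {
  start <- as.POSIXct(sprintf("%d-01-01 00:00:00", year), tz = "UTC")
  end <- as.POSIXct(sprintf("%d-01-01 00:00:00", year + 1), tz = "UTC")
  seq(start, end - 1, by = 3600)
}

#' Gridded population counts
#'
#' @param grid An [ab_grid()].
#' @param counts `[lat, lon]` matrix of person counts (non-negative, finite).
#' @return An object of class `ab_pop_grid`.
#' @export
pop_grid <- function(grid, counts) {
  counts <- as.matrix(counts)
  if (!all(dim(counts) == c(grid$n_lat, grid$n_lon)))
    stop("counts must be an [n_lat, n_lon] matrix", call. = FALSE)
  if (anyNA(counts) || any(!is.finite(counts)) || any(counts < 0))
    stop("population counts must be finite and non-negative", call. = FALSE)
  structure(list(grid = grid, counts = counts), class = "ab_pop_grid")
}

#' @export
print.ab_pop_grid <- function(x, ...) {
  cat(sprintf("<ab_pop_grid> %d x %d cells, total %.4g persons\n",
              x$grid$n_lat, x$grid$n_lon, sum(x$counts)))
  invisible(x)
}

#' Standard adult age brackets
#'
#' The twelve 5-year brackets used by the exposure-response functions:
#' 25-29 through 75-79, plus 80+.
#' @return Character vector of bracket labels.
#' @export
age_brackets <- function() {
  c(paste(seq(25, 75, 5), seq(29, 79, 5), sep = "-"), "80+")
}

#' National age-structure table
#'
#' Fraction of total population in each 5-year adult bracket, with
#' lower/mid/upper variants used by the uncertainty envelope.
#'
#' @param df Data frame with columns `bracket`, `lower`, `mid`, `upper`.
#' @return Validated data frame of class `ab_age_structure`.
#' @export
age_structure <- function(df) {
  need <- c("bracket", "lower", "mid", "upper")
  if (!all(need %in% names(df)))
    stop("age structure needs columns bracket, lower, mid, upper",
         call. = FALSE)
  df <- df[match(age_brackets(), df$bracket), need]
  if (anyNA(df$bracket))
    stop("age structure must cover every bracket 25-29 ... 80+",
         call. = FALSE)
  for (v in c("lower", "mid", "upper"))
    if (any(df[[v]] < 0)) stop("age fractions must be >= 0", call. = FALSE)
  if (any(df$lower > df$mid + 1e-12) || any(df$mid > df$upper + 1e-12))
    stop("age fractions must satisfy lower <= mid <= upper", call. = FALSE)
  if (sum(df$mid) > 1 + 1e-9)
    stop("mid age fractions must sum to at most 1", call. = FALSE)
  rownames(df) <- NULL
  class(df) <- c("ab_age_structure", "data.frame")
  df
}

#' Cause-specific baseline mortality and morbidity rates
#'
#' Long table of baseline rates per 100,000 population per year, by cause
#' (`NCD_LRI` for the PM2.5 outcome, `COPD` for the O3 outcome), age bracket,
#' and metric (`MORT`, `YLL`, `YLD`), each with lower/mid/upper variants.
#' Rates stay on the per-100,000 scale in this table; the burden pipeline
#' converts to per-person exactly once at ingestion.
#'
#' @param df Data frame with columns `cause`, `bracket`, `metric`,
#'   `lower`, `mid`, `upper`.
#' @return Validated data frame of class `ab_baseline_rates`.
#' @export
baseline_rates <- function(df) {
  need <- c("cause", "bracket", "metric", "lower", "mid", "upper")
  if (!all(need %in% names(df)))
    stop("baseline rates need columns cause, bracket, metric, lower, mid, upper",
         call. = FALSE)
  df <- as.data.frame(df)[, need]
  if (!all(df$cause %in% c("NCD_LRI", "COPD")))
    stop("cause must be NCD_LRI or COPD", call. = FALSE)
  if (!all(df$metric %in% c("MORT", "YLL", "YLD")))
    stop("metric must be MORT, YLL or YLD", call. = FALSE)
  for (v in c("lower", "mid", "upper"))
    if (any(df[[v]] < 0)) stop("rates must be non-negative", call. = FALSE)
  if (any(df$lower > df$mid + 1e-9) || any(df$mid > df$upper + 1e-9))
    stop("rates must satisfy lower <= mid <= upper", call. = FALSE)
  rownames(df) <- NULL
  class(df) <- c("ab_baseline_rates", "data.frame")
  df
}

# rate lookup: matrix [bracket, metric] for one cause and variant,
# per-person scale (single division by 1e5 -- the only place it happens)
rates_per_person <- function(rates, cause, variant) {
  sub <- rates[rates$cause == cause, ]
  if (nrow(sub) == 0L)
    stop(sprintf("no baseline rates for cause '%s'", cause), call. = FALSE)
  br <- age_brackets()
  out <- matrix(NA_real_, length(br), 3,
                dimnames = list(br, c("MORT", "YLL", "YLD")))
  for (m in colnames(out)) {
    s <- sub[sub$metric == m, ]
    out[, m] <- s[[variant]][match(br, s$bracket)]
  }
  if (anyNA(out))
    stop(sprintf("baseline rates for cause '%s' do not cover every bracket and metric",
                 cause), call. = FALSE)
  out / 1e5
}
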