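#' Paired model-observation sample
#'
#' @param model,observed Equal-length numeric vectors of matched values;
#'   pairs with a missing observation are dropped.
#' @return Object of class `ab_paired` with elements `model`, `observed`,
#'   `n`.
#' @export
paired_sample <- function(model, observed) {
  if (length(model) != length(observed))
    stop("model and observed sequences must have equal length", call. = FALSE)
  keep <- !is.na(model) & !is.na(observed)
  model <- model[keep]
  observed <- observed[keep]
  if (length(model) < 1L)
    stop("empty paired sample", call. = FALSE)
  structure(list(model = model, observed = observed, n = length(model)),
            class = "ab_paired")
}

#' Match stations to a simulated exposure field
#'
#' Each station is matched to its nearest grid cell; the model value is that
#' cell's exposure and the observed value is the station's mean over its
#' non-missing observations (annual mean for a year of data). Several
#' stations falling in one cell each contribute a pair sharing the model
#' value. Hourly pairing against an hourly field is available via
#' `mode = "hourly"`.
#'
#' @param exposure An [exposure_field()], or an hourly [conc_field()] when
#'   `mode = "hourly"`.
#' @param st An [stations()] table.
#' @param mode `"annual"` (default) or `"hourly"`.
#' @return An [paired_sample()].
#' @export
pair_stations <- function(exposure, st, mode = c("annual", "hourly")) {
  mode <- match.arg(mode)
  sites <- station_sites(st)
  grid <- exposure$grid
  b <- grid_bounds(grid)
  inb <- sites$lat >= b["lat_min"] & sites$lat <= b["lat_max"] &
    sites$lon >= b["lon_min"] & sites$lon <= b["lon_max"]
  sites <- sites[inb, ]
  if (nrow(sites) == 0L)
    stop("no stations inside the grid bounds", call. = FALSE)
  model <- numeric(0)
  observed <- numeric(0)
  df <- as.data.frame(st)
  for (i in seq_len(nrow(sites))) {
    ij <- nearest_cell(sites$lat[i], sites$lon[i], grid)
    obs <- df$value[df$station_id == sites$station_id[i]]
    if (mode == "annual") {
      if (all(is.na(obs))) next
      model <- c(model, exposure$values[ij[1], ij[2]])
      observed <- c(observed, mean(obs, na.rm = TRUE))
    } else {
      if (inherits(exposure, "ab_exposure") || exposure$annual)
        stop("hourly pairing needs an hourly concentration field",
             call. = FALSE)
      ts_st <- df$timestamp[df$station_id == sites$station_id[i]]
      idx <- match(as.numeric(ts_st), as.numeric(exposure$time))
      ok <- !is.na(idx) & !is.na(obs)
      mvals <- matrix(exposure$values,
                      nrow = grid$n_lat * grid$n_lon)[
                        (ij[2] - 1L) * grid$n_lat + ij[1], idx[ok]]
      model <- c(model, mvals)
      observed <- c(observed, obs[ok])
    }
  }
  paired_sample(model, observed)
}

check_positive_sums <- function(sample) {
  if (sum(sample$model) <= 0 || sum(sample$observed) <= 0)
    stop("metric undefined: model and observed sums must be positive",
         call. = FALSE)
}

#' Normalized mean bias factor (NMBF)
#'
#' Symmetric, scale-invariant bias factor: when the model mean is at least
#' the observed mean, `NMBF = (sum(M) - sum(O)) / sum(O)`; otherwise
#' `NMBF = (sum(M) - sum(O)) / sum(M)`. A model overestimating by a factor
#' F gives `NMBF = F - 1`; underestimating by F gives `1 - F`.
#'
#' @param sample An [paired_sample()].
#' @return Dimensionless factor.
#' @export
nmbf <- function(sample) {
  check_positive_sums(sample)
  sm <- sum(sample$model)
  so <- sum(sample$observed)
  if (mean(sample$model) >= mean(sample$observed)) (sm - so) / so
  else (sm - so) / sm
}

#' Normalized mean absolute error factor (NMAEF)
#'
#' `sum(|M - O|)` divided by `sum(O)` when the model mean is at least the
#' observed mean, else by `sum(M)`. Always at least `|NMBF|`.
#'
#' @param sample An [paired_sample()].
#' @return Dimensionless factor.
#' @export
nmaef <- function(sample) {
  check_positive_sums(sample)
  num <- sum(abs(sample$model - sample$observed))
  if (mean(sample$model) >= mean(sample$observed)) num / sum(sample$observed)
  else num / sum(sample$model)
}

#' Model-evaluation report
#'
#' Convenience wrapper producing one evaluation row per (pollutant, domain):
#' pairs stations against a simulated exposure field and computes NMBF and
#' NMAEF.
#'
#' @param exposure An [exposure_field()].
#' @param st An [stations()] table.
#' @param domain Label for the evaluated domain (e.g. region name).
#' @return One-row data frame: `pollutant, domain, n_stations, nmbf, nmaef`.
#' @export
evaluate_model <- function(exposure, st, domain = "all") {
  sample <- pair_stations(exposure, st)
  data.frame(pollutant = exposure$pollutant, domain = domain,
             n_stations = sample$n, nmbf = nmbf(sample),
             nmaef = nmaef(sample))
}
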