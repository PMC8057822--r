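#' GEMM exposure-response parameters
#'
#' Loads the Global Exposure Mortality Model (GEMM) parameter set for
#' non-accidental mortality (non-communicable disease plus lower respiratory
#' infection, NCD+LRI): one row per 5-year age bracket with the log-risk
#' coefficient `theta` (and its lower/upper 95% bounds), and the shape
#' parameters `alpha`, `mu`, `nu` (all in ug m-3). The packaged default
#' (`inst/extdata/gemm_ncd_lri.csv`) is the China-cohort-inclusive set.
#'
#' @param path CSV with columns `age_bracket, theta, theta_lower,
#'   theta_upper, alpha, mu, nu` (a `theta_se` column is kept if present);
#'   default is the packaged parameter file.
#' @param cf Counterfactual PM2.5 exposure (ug m-3) below which no excess
#'   risk is assumed; default 2.4.
#' @return Object of class `ab_gemm_params`.
#' @export
gemm_params <- function(path = system.file("extdata", "gemm_ncd_lri.csv",
                                           package = "airburden"),
                        cf = 2.4) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("age_bracket", "theta", "theta_lower", "theta_upper",
            "alpha", "mu", "nu")
  if (!all(need %in% names(df)))
    stop("GEMM parameter file needs columns age_bracket, theta, theta_lower, theta_upper, alpha, mu, nu",
         call. = FALSE)
  df <- df[match(age_brackets(), df$age_bracket), ]
  if (anyNA(df$age_bracket))
    stop("GEMM parameters must cover every bracket 25-29 ... 80+",
         call. = FALSE)
  if (any(df$alpha <= 0) || any(df$nu <= 0))
    stop("GEMM alpha and nu must be positive", call. = FALSE)
  if (any(df$theta_lower > df$theta + 1e-12) ||
      any(df$theta > df$theta_upper + 1e-12))
    stop("GEMM theta bounds must satisfy lower <= theta <= upper",
         call. = FALSE)
  if (!is.finite(cf) || cf < 0)
    stop("counterfactual must be non-negative", call. = FALSE)
  rownames(df) <- NULL
  structure(list(table = df, cf = cf), class = "ab_gemm_params")
}

#' Ozone hazard-ratio risk parameters
#'
#' Log-linear hazard ratio per 10 ppb of 6mDM8h ozone for COPD mortality,
#' with its 95% uncertainty interval, and the ozone counterfactual.
#'
#' @param hr,hr_lower,hr_upper Hazard ratio per 10 ppb (default
#'   1.06, 95UI 1.02-1.10).
#' @param cf Counterfactual 6mDM8h exposure in ppb (default 35.7).
#' @return Object of class `ab_o3_risk`.
#' @export
ozone_risk <- function(hr = 1.06, hr_lower = 1.02, hr_upper = 1.10,
                       cf = 35.7) {
  if (!(1 < hr_lower && hr_lower <= hr && hr <= hr_upper))
    stop("hazard ratio bounds must satisfy 1 < lower <= mid <= upper",
         call. = FALSE)
  if (!is.finite(cf) || cf < 0)
    stop("counterfactual must be non-negative", call. = FALSE)
  structure(list(hr = hr, hr_lower = hr_lower, hr_upper = hr_upper, cf = cf),
            class = "ab_o3_risk")
}

#' Excess exposure above the counterfactual
#'
#' `z = max(0, exposure - cf)`: no excess risk is assumed at or below the
#' counterfactual level (2.4 ug m-3 for PM2.5, 35.7 ppb for 6mDM8h ozone).
#'
#' @param exposure Exposure value(s), scalar/vector/matrix.
#' @param cf Counterfactual level.
#' @return Same shape as `exposure`.
#' @export
hazard_z <- function(exposure, cf) {
  pmax(0, exposure - cf)
}

#' GEMM relative risk
#'
#' `RR(z) = exp[ theta * log(1 + z/alpha) / (1 + exp((mu - z)/nu)) ]`:
#' supra-linear at low exposure, flattening at high exposure. `RR(0) = 1`
#' exactly and RR is strictly increasing in `z` for `theta > 0`.
#'
#' @param z Excess exposure (ug m-3), any shape, `z >= 0`.
#' @param theta Log-risk coefficient (variant-specific value).
#' @param alpha,mu,nu Shape parameters (ug m-3).
#' @return Relative risk, same shape as `z`.
#' @examples
#' gemm_rr(70.4, theta = 0.1430, alpha = 1.6, mu = 15.5, nu = 36.8) # ~1.5595
#' @export
gemm_rr <- function(z, theta, alpha, mu, nu) {
  exp(theta * log1p(z / alpha) / (1 + exp((mu - z) / nu)))
}

# variant theta for one bracket
gemm_theta <- function(params, bracket, variant = c("mid", "lower", "upper")) {
  variant <- match.arg(variant)
  row <- params$table[params$table$age_bracket == bracket, ]
  if (nrow(row) != 1L)
    stop(sprintf("unknown age bracket '%s'", bracket), call. = FALSE)
  switch(variant, mid = row$theta, lower = row$theta_lower,
         upper = row$theta_upper)
}

#' GEMM relative risk for an age bracket
#'
#' @param z Excess PM2.5 exposure (ug m-3).
#' @param params An [gemm_params()] object.
#' @param bracket Age bracket label, e.g. `"60-64"`.
#' @param variant `"mid"` (default), `"lower"` or `"upper"` theta bound.
#' @return Relative risk, same shape as `z`.
#' @export
gemm_rr_bracket <- function(z, params, bracket,
                            variant = c("mid", "lower", "upper")) {
  variant <- match.arg(variant)
  row <- params$table[params$table$age_bracket == bracket, ]
  if (nrow(row) != 1L)
    stop(sprintf("unknown age bracket '%s'", bracket), call. = FALSE)
  gemm_rr(z, gemm_theta(params, bracket, variant), row$alpha, row$mu, row$nu)
}

#' Population attributable count for PM2.5
#'
#' `PAF = P * (1 - 1/RR)`: the attributable fraction `1 - 1/RR` scaled by
#' the bracket population.
#'
#' @param z Excess PM2.5 exposure (ug m-3).
#' @param params An [gemm_params()] object.
#' @param bracket Age bracket label.
#' @param population Persons in the bracket (same shape as `z` or scalar).
#' @param variant Theta variant.
#' @return Attributable person count, in `[0, population)`.
#' @export
pm25_paf <- function(z, params, bracket, population,
                     variant = c("mid", "lower", "upper")) {
  rr <- gemm_rr_bracket(z, params, bracket, variant)
  population * (1 - 1 / rr)
}

#' Population attributable count for ozone
#'
#' `PAF = P * (1 - exp(-z * log(HR) / 10))` with HR the hazard ratio per
#' 10 ppb. At `z = 10` the attributable fraction is exactly `1 - 1/HR`.
#'
#' @param z Excess 6mDM8h exposure (ppb).
#' @param risk An [ozone_risk()] object.
#' @param population Persons in the bracket.
#' @param variant `"mid"`, `"lower"` or `"upper"` hazard-ratio bound.
#' @return Attributable person count, in `[0, population)`.
#' @export
o3_paf <- function(z, risk, population,
                   variant = c("mid", "lower", "upper")) {
  variant <- match.arg(variant)
  hr <- switch(variant, mid = risk$hr, lower = risk$hr_lower,
               upper = risk$hr_upper)
  population * (1 - exp(-z * log(hr) / 10))
}

#' Attributable burden from an attributable count
#'
#' Multiplies an attributable person count by the per-person baseline rate
#' of the requested metric (`MORT`, `YLL`, `YLD`; rates are supplied per
#' 100,000 and converted exactly once). `DALY` is returned as `YLL + YLD`.
#'
#' @param paf_count Attributable person count.
#' @param rates An [baseline_rates()] table.
#' @param cause `"NCD_LRI"` or `"COPD"`.
#' @param bracket Age bracket label.
#' @param metric `"MORT"`, `"YLL"`, `"YLD"` or `"DALY"`.
#' @param variant Rate variant.
#' @return Attributable amount (deaths or years).
#' @export
attributable_burden <- function(paf_count, rates, cause, bracket,
                                metric = c("MORT", "YLL", "YLD", "DALY"),
                                variant = c("mid", "lower", "upper")) {
  metric <- match.arg(metric)
  variant <- match.arg(variant)
  rp <- rates_per_person(rates, cause, variant)
  if (!bracket %in% rownames(rp))
    stop(sprintf("unknown age bracket '%s'", bracket), call. = FALSE)
  if (metric == "DALY")
    paf_count * (rp[bracket, "YLL"] + rp[bracket, "YLD"])
  else
    paf_count * rp[bracket, metric]
}

burden_metrics <- c("MORT", "YLL", "YLD", "DALY")

#' Attributable-burden pipeline
#'
#' Runs the full chain per grid cell and age bracket: excess exposure above
#' the counterfactual, relative risk (GEMM for PM2.5; log-linear hazard
#' ratio for ozone), attributable count, and burden in MORT / YLL / YLD /
#' DALYs. The three uncertainty variants are evaluated simultaneously at
#' their lower, mid and upper bounds (exposure-outcome association, baseline
#' rates, and age fractions move together), giving a conservative 95%
#' envelope.
#'
#' @param exposure An [exposure_field()] (annual-mean PM2.5 or 6mDM8h O3).
#' @param pop An [pop_grid()] on the same grid.
#' @param ages An [age_structure()] table.
#' @param rates An [baseline_rates()] table covering the pollutant's cause.
#' @param risk An [gemm_params()] (PM2.5) or [ozone_risk()] (O3) object.
#' @param variants Variants to evaluate (default all three).
#' @return Object of class `ab_burden`: per-variant arrays
#'   `[lat, lon, bracket, metric]` of attributable amounts plus
#'   `[lat, lon, bracket]` attributable counts, with the pollutant, cause
#'   and grid recorded.
#' @export
burden_pipeline <- function(exposure, pop, ages, rates, risk,
                            variants = c("lower", "mid", "upper")) {
  stopifnot_same_grid(exposure$grid, pop$grid)
  pm <- exposure$pollutant == "pm25"
  if (pm && !inherits(risk, "ab_gemm_params"))
    stop("PM2.5 burden needs GEMM parameters", call. = FALSE)
  if (!pm && !inherits(risk, "ab_o3_risk"))
    stop("O3 burden needs ozone risk parameters", call. = FALSE)
  cause <- if (pm) "NCD_LRI" else "COPD"
  br <- age_brackets()
  if (pm && !setequal(params_brackets <- risk$table$age_bracket, br))
    stop("configuration error: GEMM parameters do not cover the age brackets",
         call. = FALSE)
  grid <- exposure$grid
  z <- hazard_z(exposure$values, risk$cf)
  dims <- c(grid$n_lat, grid$n_lon, length(br), length(burden_metrics))
  out <- list()
  for (v in variants) {
    rp <- rates_per_person(rates, cause, v)
    arr <- array(0, dims,
                 dimnames = list(NULL, NULL, br, burden_metrics))
    paf <- array(0, dims[1:3], dimnames = list(NULL, NULL, br))
    for (b in br) {
      frac <- ages[[v]][match(b, ages$bracket)]
      pop_b <- pop$counts * frac
      afrac <- if (pm) {
        1 - 1 / gemm_rr_bracket(z, risk, b, v)
      } else {
        hrv <- switch(v, mid = risk$hr, lower = risk$hr_lower,
                      upper = risk$hr_upper)
        1 - exp(-z * log(hrv) / 10)
      }
      cnt <- pop_b * afrac
      paf[, , b] <- cnt
      for (m in c("MORT", "YLL", "YLD"))
        arr[, , b, m] <- cnt * rp[b, m]
      arr[, , b, "DALY"] <- arr[, , b, "YLL"] + arr[, , b, "YLD"]
    }
    out[[v]] <- list(burden = arr, paf = paf)
  }
  structure(list(grid = grid, pollutant = exposure$pollutant, cause = cause,
                 scenario_id = exposure$scenario_id, brackets = br,
                 metrics = burden_metrics, variants = variants,
                 by_variant = out),
            class = "ab_burden")
}

#' @export
print.ab_burden <- function(x, ...) {
  tot <- burden_total(x)
  cat(sprintf("<ab_burden> %s (%s), scenario '%s'\n", toupper(x$pollutant),
              x$cause, x$scenario_id))
  print(round(tot, 1))
  invisible(x)
}

#' Total burden over a region
#'
#' Sums attributable amounts over cells (mask-weighted) and age brackets.
#'
#' @param burden An `ab_burden` from [burden_pipeline()].
#' @param mask Optional [region_mask()].
#' @return Matrix `[metric, variant]` of totals.
#' @export
burden_total <- function(burden, mask = NULL) {
  w <- if (is.null(mask)) 1 else mask$weights
  out <- matrix(NA_real_, length(burden$metrics), length(burden$variants),
                dimnames = list(burden$metrics, burden$variants))
  for (v in burden$variants) {
    arr <- burden$by_variant[[v]]$burden
    for (m in burden$metrics) {
      sl <- arr[, , , m, drop = FALSE]
      # sum over brackets then weight cells
      cell <- apply(array(sl, dim = dim(arr)[1:3]), c(1, 2), sum)
      out[m, v] <- sum(cell * w)
    }
  }
  out
}

#' Monte-Carlo uncertainty for regional burden totals
#'
#' Optional alternative to the simultaneous lower/mid/upper envelope:
#' samples the exposure-outcome association (normal theta, log-normal hazard
#' ratio), baseline rates and age fractions (normal, truncated at zero, with
#' standard deviation `(upper - lower)/3.92`) and returns empirical 2.5/50/
#' 97.5 percentiles of the regional burden totals.
#'
#' @inheritParams burden_pipeline
#' @param mask Optional [region_mask()].
#' @param n_draws Number of Monte-Carlo draws (default 200).
#' @param seed Integer seed (required for reproducibility).
#' @return Array `[metric, quantile]` with quantiles `lower`, `mid`,
#'   `upper`.
#' @export
burden_montecarlo <- function(exposure, pop, ages, rates, risk, mask = NULL,
                              n_draws = 200, seed = 1) {
  set.seed(seed)
  pm <- exposure$pollutant == "pm25"
  cause <- if (pm) "NCD_LRI" else "COPD"
  br <- age_brackets()
  z <- hazard_z(exposure$values, risk$cf)
  w <- if (is.null(mask)) 1 else mask$weights
  rsub <- rates[rates$cause == cause, ]
  draws <- matrix(NA_real_, n_draws, length(burden_metrics),
                  dimnames = list(NULL, burden_metrics))
  sd_from_ui <- function(lower, upper) (upper - lower) / 3.92
  for (d in seq_len(n_draws)) {
    tot <- c(MORT = 0, YLL = 0, YLD = 0, DALY = 0)
    if (!pm) {
      log_hr <- stats::rnorm(1, log(risk$hr),
                             sd_from_ui(log(risk$hr_lower),
                                        log(risk$hr_upper)))
      afrac_all <- 1 - exp(-z * log_hr / 10)
      afrac_all[afrac_all < 0] <- 0
    }
    for (b in br) {
      i <- match(b, ages$bracket)
      frac <- max(0, stats::rnorm(1, ages$mid[i],
                                  sd_from_ui(ages$lower[i], ages$upper[i])))
      pop_b <- pop$counts * frac
      if (pm) {
        row <- risk$table[risk$table$age_bracket == b, ]
        se <- if (!is.null(row$theta_se) && is.finite(row$theta_se))
          row$theta_se else sd_from_ui(row$theta_lower, row$theta_upper)
        th <- stats::rnorm(1, row$theta, se)
        afrac <- 1 - 1 / gemm_rr(z, th, row$alpha, row$mu, row$nu)
        afrac[afrac < 0] <- 0
      } else {
        afrac <- afrac_all
      }
      cnt <- sum(pop_b * afrac * w)
      for (m in c("MORT", "YLL", "YLD")) {
        s <- rsub[rsub$metric == m & rsub$bracket == b, ]
        rate <- max(0, stats::rnorm(1, s$mid, sd_from_ui(s$lower, s$upper)))
        tot[m] <- tot[m] + cnt * rate / 1e5
      }
    }
    tot["DALY"] <- tot["YLL"] + tot["YLD"]
    draws[d, ] <- tot
  }
  out <- apply(draws, 2, stats::quantile, probs = c(0.025, 0.5, 0.975),
               names = FALSE)
  t(array(out, dim = c(3, length(burden_metrics)),
          dimnames = list(c("lower", "mid", "upper"), burden_metrics)))
}
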