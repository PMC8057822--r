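#' Aggregate per-cell burden to regions
#'
#' Mask-weighted sums of attributable counts per region, with burden rates
#' per 100,000 recomputed from the aggregated counts and populations (counts
#' are aggregated first; rates are never averaged).
#'
#' @param burden An `ab_burden` from [burden_pipeline()].
#' @param masks Named list of [region_mask()]s.
#' @param pop An [pop_grid()].
#' @return Long data frame of class `ab_region_burden`: one row per
#'   (region, metric, variant) with `count`, `population`, `rate_per_100k`,
#'   plus the scenario, pollutant and cause labels.
#' @export
aggregate_burden <- function(burden, masks, pop) {
  stopifnot_same_grid(burden$grid, pop$grid)
  rows <- list()
  for (id in names(masks)) {
    mask <- masks[[id]]
    stopifnot_same_grid(burden$grid, mask$grid)
    population <- sum(pop$counts * mask$weights)
    if (population <= 0) {
      warning(sprintf("region '%s' has zero population; skipped", id))
      next
    }
    tot <- burden_total(burden, mask)
    for (m in burden$metrics) for (v in burden$variants) {
      rows[[length(rows) + 1L]] <- data.frame(
        region = id, scenario = burden$scenario_id,
        pollutant = burden$pollutant, cause = burden$cause,
        metric = m, variant = v, count = tot[m, v],
        population = population,
        rate_per_100k = tot[m, v] / population * 1e5)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("ab_region_burden", "data.frame")
  out
}

#' Population-weighted exposure per region
#'
#' @param exposure An [exposure_field()].
#' @param masks Named list of [region_mask()]s.
#' @param pop An [pop_grid()].
#' @return Data frame: `region, scenario, pollutant, metric, pw_exposure`.
#' @export
aggregate_exposure <- function(exposure, masks, pop) {
  rows <- lapply(names(masks), function(id) {
    data.frame(region = id, scenario = exposure$scenario_id,
               pollutant = exposure$pollutant, metric = exposure$metric,
               pw_exposure = population_weighted_mean(exposure, pop,
                                                      masks[[id]]))
  })
  do.call(rbind, rows)
}

#' Avoided burden between a control and a scenario
#'
#' Differences aggregated burden tables bound-to-bound (lower minus lower,
#' mid minus mid, upper minus upper, matching the envelope construction) and
#' adds a combined row per region/metric/variant summing the pollutants
#' (counts are additive; an ozone term may be negative when ozone exposure
#' rises under a precursor cut).
#'
#' @param control,scenario `ab_region_burden` tables (may contain both
#'   pollutants, stacked with `rbind`) for the same regions and structure.
#' @return Data frame of class `ab_comparison`: per (region, pollutant,
#'   metric, variant) the avoided `count` (control minus scenario) and
#'   avoided rate per 100,000; `pollutant = "combined"` rows hold the sums
#'   over pollutants.
#' @export
avoided_burden <- function(control, scenario) {
  key <- function(df) paste(df$region, df$pollutant, df$cause, df$metric,
                            df$variant)
  if (nrow(control) != nrow(scenario) ||
      !setequal(key(control), key(scenario)))
    stop("comparison error: control and scenario tables have different structure",
         call. = FALSE)
  scn <- scenario[match(key(control), key(scenario)), ]
  out <- data.frame(
    region = control$region, scenario = scn$scenario[1],
    pollutant = control$pollutant, cause = control$cause,
    metric = control$metric, variant = control$variant,
    count = control$count - scn$count,
    population = control$population,
    rate_per_100k = (control$count - scn$count) / control$population * 1e5)
  comb_key <- paste(out$region, out$metric, out$variant)
  agg <- stats::aggregate(out$count, by = list(k = comb_key), FUN = sum)
  first <- out[!duplicated(comb_key), ]
  first <- first[match(agg$k, comb_key[!duplicated(comb_key)]), ]
  comb <- data.frame(
    region = first$region, scenario = first$scenario,
    pollutant = "combined", cause = "ALL",
    metric = first$metric, variant = first$variant,
    count = agg$x, population = first$population,
    rate_per_100k = agg$x / first$population * 1e5)
  res <- rbind(out, comb)
  rownames(res) <- NULL
  class(res) <- c("ab_comparison", "data.frame")
  res
}

fmt_hundreds <- function(x) {
  formatC(round_half_up(x / 100) * 100, format = "d", big.mark = ",")
}

#' Summary tables for a scenario set
#'
#' One row per (region, scenario): population-weighted exposures in the
#' control and scenario, the absolute and percent exposure change (percent
#' rounded half-up to integers), and avoided premature deaths with the 95%
#' interval (counts rounded to the nearest hundred for the formatted
#' column).
#'
#' @param control_exposure,scenario_exposure Tables from
#'   [aggregate_exposure()] for one pollutant.
#' @param comparison An `ab_comparison` from [avoided_burden()].
#' @param pollutant Which pollutant's avoided burden to tabulate
#'   (`"pm25"`, `"o3"` or `"combined"`).
#' @return Data frame with raw and formatted columns; the `markdown`
#'   attribute holds a ready-to-print markdown table.
#' @export
paper_tables <- function(control_exposure, scenario_exposure, comparison,
                         pollutant = "combined") {
  stopifnot(all(control_exposure$region == scenario_exposure$region))
  cmp <- comparison[comparison$pollutant == pollutant &
                      comparison$metric == "MORT", ]
  rows <- list()
  for (i in seq_len(nrow(control_exposure))) {
    reg <- control_exposure$region[i]
    pc <- control_exposure$pw_exposure[i]
    ps <- scenario_exposure$pw_exposure[i]
    pct <- if (pc > 0) round_half_up(100 * (pc - ps) / pc) else 0
    cm <- cmp[cmp$region == reg, ]
    gv <- function(v) if (nrow(cm)) cm$count[cm$variant == v] else NA_real_
    rows[[i]] <- data.frame(
      region = reg, scenario = scenario_exposure$scenario[i],
      pw_control = pc, pw_scenario = ps, delta = pc - ps,
      percent_change = pct,
      avoided_mort = gv("mid"), avoided_mort_lower = gv("lower"),
      avoided_mort_upper = gv("upper"),
      avoided_mort_fmt = sprintf("%s (95UI: %s-%s)", fmt_hundreds(gv("mid")),
                                 fmt_hundreds(gv("lower")),
                                 fmt_hundreds(gv("upper"))))
  }
  out <- do.call(rbind, rows)
  hdr <- c("Region", "Exposure (control)", "Exposure (scenario)",
           "Change (%)", "Avoided deaths (95UI)")
  md <- c(paste0("| ", paste(hdr, collapse = " | "), " |"),
          paste0("|", paste(rep("---", length(hdr)), collapse = "|"), "|"),
          sprintf("| %s | %.1f | %.1f | %d%% | %s |", out$region,
                  out$pw_control, out$pw_scenario, out$percent_change,
                  out$avoided_mort_fmt))
  attr(out, "markdown") <- paste(md, collapse = "\n")
  out
}
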