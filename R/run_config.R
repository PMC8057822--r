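#' Read a run configuration file
#'
#' YAML key-value configuration shared by the command-line entry point and
#' scripted runs: pollutant counterfactuals, the risk-parameter and rate
#' table paths, the scenario list, seed and output directory. Unknown keys
#' are kept as-is.
#'
#' @param path YAML file.
#' @return Validated list of class `ab_run_config` with defaults filled in:
#'   `cf_pm25` (2.4), `cf_o3` (35.7), `seed` (1), `out_dir` (`"."`),
#'   `scenarios` (character vector), `gemm_csv` (packaged default).
#' @export
read_run_config <- function(path) {
  cfg <- if (is.null(path)) list() else yaml::read_yaml(path)
  cfg$cf_pm25 <- cfg$cf_pm25 %||% 2.4
  cfg$cf_o3 <- cfg$cf_o3 %||% 35.7
  cfg$seed <- as.integer(cfg$seed %||% 1L)
  cfg$out_dir <- cfg$out_dir %||% "."
  cfg$scenarios <- cfg$scenarios %||% c("RES", "AGR", "TRA", "IND")
  cfg$gemm_csv <- cfg$gemm_csv %||%
    system.file("extdata", "gemm_ncd_lri.csv", package = "airburden")
  if (cfg$cf_pm25 <= 0 || cfg$cf_o3 <= 0)
    stop("counterfactuals must be positive", call. = FALSE)
  if (is.na(cfg$seed))
    stop("seed must be an integer", call. = FALSE)
  class(cfg) <- "ab_run_config"
  cfg
}
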