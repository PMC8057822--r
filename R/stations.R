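#' Station observation table
#'
#' Long table of monitoring observations: one row per station-timestamp.
#' Missing observations are explicit `NA` values (the CSV sentinel `-999`
#' is also recognized on read) and are excluded pairwise during evaluation.
#'
#' @param df Data frame with columns `station_id`, `lat`, `lon`,
#'   `timestamp` (`POSIXct` UTC), `value`.
#' @return Validated data frame of class `ab_stations`.
#' @export
stations <- function(df) {
  need <- c("station_id", "lat", "lon", "timestamp", "value")
  if (!all(need %in% names(df)))
    stop("station table needs columns station_id, lat, lon, timestamp, value",
         call. = FALSE)
  df <- as.data.frame(df)[, need]
  df$station_id <- as.character(df$station_id)
  if (anyNA(df$lat) || anyNA(df$lon))
    stop("station coordinates must be complete", call. = FALSE)
  class(df) <- c("ab_stations", "data.frame")
  df
}

#' Read station observations from CSV
#'
#' @param path CSV with columns `station_id, lat, lon, timestamp, value`;
#'   timestamps in `YYYY-mm-dd HH:MM:SS` (UTC). Values of `-999` are read
#'   as missing.
#' @return An [stations()] table.
#' @export
read_stations <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$timestamp <- as.POSIXct(df$timestamp, tz = "UTC")
  df$value[!is.na(df$value) & df$value == -999] <- NA_real_
  stations(df)
}

#' Write station observations to CSV
#'
#' Missing values are written as the explicit sentinel `-999`.
#'
#' @param st An [stations()] table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_stations <- function(st, path) {
  out <- as.data.frame(st)
  out$timestamp <- format(out$timestamp, "%Y-%m-%d %H:%M:%S", tz = "UTC")
  out$value[is.na(out$value)] <- -999
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

# per-station metadata (one row per station)
station_sites <- function(st) {
  unique(as.data.frame(st)[, c("station_id", "lat", "lon")])
}
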