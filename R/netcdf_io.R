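#' Write a concentration field to NetCDF
#'
#' CF-style layout: dimensions `(lon, lat, time)` for hourly fields or
#' `(lon, lat)` for annual fields, coordinate variables with degree units,
#' and a mandatory `units` attribute on the concentration variable
#' (`ug m-3` for PM2.5, `ppb` for O3). Round trips through
#' [read_concentration_field()] are bit-identical.
#'
#' @param field An [conc_field()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_concentration_field <- function(field, path) {
  dim_lat <- ncdf4::ncdim_def("lat", "degrees_north", field$grid$lat)
  dim_lon <- ncdf4::ncdim_def("lon", "degrees_east", field$grid$lon)
  varname <- field$pollutant
  if (field$annual) {
    v <- ncdf4::ncvar_def(varname, conc_units(field$pollutant),
                          list(dim_lon, dim_lat), prec = "double")
    nc <- ncdf4::nc_create(path, v)
    on.exit(ncdf4::nc_close(nc))
    # internal storage is [lat, lon]; NetCDF fastest dim is lon
    ncdf4::ncvar_put(nc, v, t(field$values))
  } else {
    origin <- format(field$time[1], "%Y-%m-%d %H:%M:%S", tz = "UTC")
    hrs <- as.numeric(difftime(field$time, field$time[1], units = "hours"))
    dim_t <- ncdf4::ncdim_def("time", sprintf("hours since %s", origin), hrs,
                              unlim = TRUE)
    v <- ncdf4::ncvar_def(varname, conc_units(field$pollutant),
                          list(dim_lon, dim_lat, dim_t), prec = "double")
    nc <- ncdf4::nc_create(path, v)
    on.exit(ncdf4::nc_close(nc))
    ncdf4::ncvar_put(nc, v, aperm(field$values, c(2, 1, 3)))
  }
  ncdf4::ncatt_put(nc, varname, "scenario_id", field$scenario_id)
  invisible(path)
}

# canonical-unit scale factor, or NA for unknown unit strings
unit_scale <- function(units, pollutant) {
  u <- gsub("µ", "u", tolower(trimws(units)))
  if (pollutant == "pm25") {
    if (u %in% c("ug m-3", "ug/m3", "ug m^-3", "micrograms per cubic meter"))
      return(1)
    if (u %in% c("mg m-3", "mg/m3")) return(1000)
  } else {
    if (u %in% c("ppb", "ppbv")) return(1)
    if (u %in% c("ppm", "ppmv")) return(1000)
  }
  NA_real_
}

#' Read a concentration field from NetCDF
#'
#' Accepts the layout written by [write_concentration_field()] (and
#' equivalent CF files). The concentration variable must carry a `units`
#' attribute; `ppm` ozone is converted to ppb (x1000) and `mg m-3` PM2.5 to
#' ug m-3. Missing variables, non-monotonic axes or unknown units raise a
#' format error naming the offender.
#'
#' @param path NetCDF file path.
#' @param pollutant `"pm25"` or `"o3"`.
#' @param varname Variable name; defaults to the pollutant name.
#' @return An [conc_field()].
#' @export
read_concentration_field <- function(path, pollutant, varname = pollutant) {
  pollutant <- match.arg(pollutant, c("pm25", "o3"))
  if (!file.exists(path))
    stop(sprintf("file not found: %s", path), call. = FALSE)
  nc <- ncdf4::nc_open(path)
  on.exit(ncdf4::nc_close(nc))
  if (!varname %in% names(nc$var))
    stop(sprintf("format error: variable '%s' missing from %s", varname, path),
         call. = FALSE)
  for (ax in c("lat", "lon"))
    if (!ax %in% names(nc$dim))
      stop(sprintf("format error: dimension '%s' missing from %s", ax, path),
           call. = FALSE)
  lat <- nc$dim$lat$vals
  lon <- nc$dim$lon$vals
  if (length(lat) > 1 && !strictly_monotonic(lat))
    stop("format error: latitude axis is not strictly monotonic",
         call. = FALSE)
  if (length(lon) > 1 && !strictly_monotonic(lon))
    stop("format error: longitude axis is not strictly monotonic",
         call. = FALSE)
  ua <- ncdf4::ncatt_get(nc, varname, "units")
  if (!isTRUE(ua$hasatt))
    stop(sprintf("format error: variable '%s' has no units attribute", varname),
         call. = FALSE)
  sc <- unit_scale(ua$value, pollutant)
  if (is.na(sc))
    stop(sprintf("format error: unknown units attribute '%s' for %s",
                 ua$value, pollutant), call. = FALSE)
  vals <- ncdf4::ncvar_get(nc, varname, collapse_degen = FALSE)
  sid <- ncdf4::ncatt_get(nc, varname, "scenario_id")
  sid <- if (isTRUE(sid$hasatt)) sid$value else "control"
  grid <- ab_grid(lat, lon)
  if ("time" %in% names(nc$dim) && nc$dim$time$len > 0) {
    tu <- nc$dim$time$units
    m <- regmatches(tu, regexec("hours since ([0-9: -]+)", tu))[[1]]
    if (length(m) < 2)
      stop(sprintf("format error: unsupported time units '%s'", tu),
           call. = FALSE)
    origin <- as.POSIXct(m[2], tz = "UTC")
    time <- origin + nc$dim$time$vals * 3600
    vals <- array(vals, dim = c(length(lon), length(lat), length(time)))
    conc_field(grid, pollutant, aperm(vals, c(2, 1, 3)) * sc, time = time,
               scenario_id = sid)
  } else {
    vals <- matrix(vals, nrow = length(lon), ncol = length(lat))
    conc_field(grid, pollutant, t(vals) * sc, scenario_id = sid)
  }
}

#' Write a population grid to NetCDF
#'
#' @param pop An [pop_grid()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_population <- function(pop, path) {
  dim_lat <- ncdf4::ncdim_def("lat", "degrees_north", pop$grid$lat)
  dim_lon <- ncdf4::ncdim_def("lon", "degrees_east", pop$grid$lon)
  v <- ncdf4::ncvar_def("population", "persons", list(dim_lon, dim_lat),
                        prec = "double")
  nc <- ncdf4::nc_create(path, v)
  on.exit(ncdf4::nc_close(nc))
  ncdf4::ncvar_put(nc, v, t(pop$counts))
  invisible(path)
}

#' Read a population grid from NetCDF
#'
#' @param path NetCDF file path written by [write_population()].
#' @return An [pop_grid()].
#' @export
read_population <- function(path) {
  if (!file.exists(path))
    stop(sprintf("file not found: %s", path), call. = FALSE)
  nc <- ncdf4::nc_open(path)
  on.exit(ncdf4::nc_close(nc))
  if (!"population" %in% names(nc$var))
    stop(sprintf("format error: variable 'population' missing from %s", path),
         call. = FALSE)
  grid <- ab_grid(nc$dim$lat$vals, nc$dim$lon$vals)
  vals <- ncdf4::ncvar_get(nc, "population", collapse_degen = FALSE)
  pop_grid(grid, t(matrix(vals, nrow = grid$n_lon, ncol = grid$n_lat)))
}

#' Write a per-cell exposure field to NetCDF
#'
#' Single-time CF layout with the exposure metric recorded in variable
#' metadata.
#'
#' @param exposure An `ab_exposure` object (see [annual_mean()],
#'   [six_m_dm8h()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_exposure_field <- function(exposure, path) {
  dim_lat <- ncdf4::ncdim_def("lat", "degrees_north", exposure$grid$lat)
  dim_lon <- ncdf4::ncdim_def("lon", "degrees_east", exposure$grid$lon)
  v <- ncdf4::ncvar_def("exposure", conc_units(exposure$pollutant),
                        list(dim_lon, dim_lat), prec = "double")
  nc <- ncdf4::nc_create(path, v)
  on.exit(ncdf4::nc_close(nc))
  ncdf4::ncvar_put(nc, v, t(exposure$values))
  ncdf4::ncatt_put(nc, "exposure", "metric", exposure$metric)
  ncdf4::ncatt_put(nc, "exposure", "pollutant", exposure$pollutant)
  ncdf4::ncatt_put(nc, "exposure", "scenario_id", exposure$scenario_id)
  invisible(path)
}
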