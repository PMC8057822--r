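#' Region membership mask on a grid
#'
#' @param region_id Label.
#' @param weights `[lat, lon]` matrix of membership weights in `[0, 1]`
#'   (boolean membership is stored as 0/1).
#' @param grid The [ab_grid()] the mask lives on.
#' @return An object of class `ab_region_mask`.
#' @export
region_mask <- function(region_id, weights, grid) {
  weights <- as.matrix(weights) * 1.0
  if (!all(dim(weights) == c(grid$n_lat, grid$n_lon)))
    stop("mask weights must be an [n_lat, n_lon] matrix", call. = FALSE)
  if (anyNA(weights) || any(weights < 0) || any(weights > 1))
    stop("mask weights must lie in [0, 1]", call. = FALSE)
  structure(list(region_id = region_id, weights = weights, grid = grid),
            class = "ab_region_mask")
}

#' Check that a set of masks forms a partition
#'
#' A partition covers every cell exactly once: per-cell weights across the
#' masks sum to 1.
#'
#' @param masks List of [region_mask()]s on one grid.
#' @param tol Tolerance on the per-cell sum (default 1e-9).
#' @return `TRUE`/`FALSE`.
#' @export
is_partition <- function(masks, tol = 1e-9) {
  total <- Reduce(`+`, lapply(masks, `[[`, "weights"))
  all(abs(total - 1) <= tol)
}

# ---- GeoJSON ----

# Pull (lon, lat) ring matrices out of a GeoJSON geometry; rings of one
# polygon are concatenated with NA separators (the form mgcv::in.out and the
# even-odd rule expect), multipolygon parts likewise.
geojson_rings <- function(geometry, feature_id = "?") {
  type <- geometry$type
  coords <- geometry$coordinates
  ring_mat <- function(ring) {
    m <- do.call(rbind, lapply(ring, function(p) c(p[[1]], p[[2]])))
    if (nrow(m) < 4)
      stop(sprintf("geometry error in feature '%s': ring with fewer than 4 positions",
                   feature_id), call. = FALSE)
    m
  }
  polys <- switch(type,
    Polygon = list(coords),
    MultiPolygon = coords,
    stop(sprintf("geometry error in feature '%s': unsupported type '%s'",
                 feature_id, type), call. = FALSE)
  )
  rings <- unlist(lapply(polys, function(poly) lapply(poly, ring_mat)),
                  recursive = FALSE)
  out <- do.call(rbind, lapply(rings, function(r) rbind(r, c(NA, NA))))
  out[-nrow(out), , drop = FALSE]
}

#' Read region features from GeoJSON
#'
#' @param path GeoJSON file containing a `FeatureCollection` of `Polygon` or
#'   `MultiPolygon` features. Each feature's `region_id` (or `name` or `id`)
#'   property becomes the region label.
#' @return Named list of geometries (ring matrices with `NA` separators),
#'   one per feature.
#' @export
read_geojson_regions <- function(path) {
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!identical(gj$type, "FeatureCollection"))
    stop("geometry error: expected a GeoJSON FeatureCollection", call. = FALSE)
  out <- list()
  for (k in seq_along(gj$features)) {
    f <- gj$features[[k]]
    id <- f$properties$region_id %||% f$properties$name %||% f$id %||%
      sprintf("region_%d", k)
    out[[id]] <- geojson_rings(f$geometry, id)
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Rasterize region geometries onto a grid
#'
#' Membership is by cell-center containment (default) or by fractional area
#' overlap approximated with an `subsample x subsample` lattice of points per
#' cell.
#'
#' @param geometries Named list of ring matrices from
#'   [read_geojson_regions()], or a path to a GeoJSON file.
#' @param grid An [ab_grid()].
#' @param mode `"center"` or `"fraction"`.
#' @param subsample Points per cell side in `"fraction"` mode (default 8).
#' @return Named list of [region_mask()]s.
#' @export
rasterize_regions <- function(geometries, grid, mode = c("center", "fraction"),
                              subsample = 8L) {
  mode <- match.arg(mode)
  if (is.character(geometries) && length(geometries) == 1L)
    geometries <- read_geojson_regions(geometries)
  if (mode == "center") {
    px <- rep(grid$lon, each = grid$n_lat)
    py <- rep(grid$lat, times = grid$n_lon)
    wt <- 1
  } else {
    lat_h <- if (grid$n_lat > 1) abs(grid$lat[2] - grid$lat[1]) else 1
    lon_h <- if (grid$n_lon > 1) abs(grid$lon[2] - grid$lon[1]) else 1
    off <- (seq_len(subsample) - 0.5) / subsample - 0.5
    sub <- expand.grid(dlat = off * lat_h, dlon = off * lon_h)
    px <- rep(rep(grid$lon, each = grid$n_lat), times = nrow(sub)) +
      rep(sub$dlon, each = grid$n_lat * grid$n_lon)
    py <- rep(rep(grid$lat, times = grid$n_lon), times = nrow(sub)) +
      rep(sub$dlat, each = grid$n_lat * grid$n_lon)
    wt <- nrow(sub)
  }
  pts <- cbind(px, py)
  lapply_named(geometries, function(id, bnd) {
    inside <- mgcv::in.out(bnd, pts)
    w <- matrix(rowSums(matrix(inside, ncol = wt)) / wt,
                nrow = grid$n_lat, ncol = grid$n_lon)
    region_mask(id, w, grid)
  })
}

lapply_named <- function(x, f) {
  out <- mapply(f, names(x), x, SIMPLIFY = FALSE)
  names(out) <- names(x)
  out
}

# rectangle helper used by the synthetic world and tests:
# closed ring (lon, lat) for [lat0, lat1] x [lon0, lon1]
rect_ring <- function(lat0, lat1, lon0, lon1) {
  cbind(c(lon0, lon1, lon1, lon0, lon0),
        c(lat0, lat0, lat1, lat1, lat0))
}

#' Write region geometries to GeoJSON
#'
#' @param geometries Named list of ring matrices (single-ring polygons).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_geojson_regions <- function(geometries, path) {
  features <- mapply(function(id, ring) {
    list(type = "Feature",
         properties = list(region_id = id),
         geometry = list(
           type = "Polygon",
           coordinates = list(lapply(seq_len(nrow(ring)),
                                     function(i) as.numeric(ring[i, ])))))
  }, names(geometries), geometries, SIMPLIFY = FALSE)
  names(features) <- NULL
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
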