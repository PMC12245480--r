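# IUCN geographic range metrics: extent of occurrence (EOO, convex hull),
# area of occupancy (AOO, 2-km occupancy grid) and the criterion-B2
# threshold category.

EARTH_RADIUS_KM <- 6371

#' Project occurrence records to planar kilometre coordinates
#'
#' Cylindrical equal-area projection centred on the points' mean longitude,
#' with the standard parallel at the points' mean latitude (spherical earth,
#' R = 6371 km). Longitudes spanning the antimeridian are unwrapped before
#' projection. Equal-area projection keeps hull and grid-cell areas faithful
#' at the scale (tens to hundreds of km) these metrics are used for.
#'
#' @param points data frame with `lon`, `lat` in WGS84 decimal degrees.
#' @return Matrix with columns `x`, `y` in km; the `y` origin is the
#'   equator, the `x` origin the mean longitude (attributes `lon0`,
#'   `lat_ts` record the projection parameters).
#' @export
project_occurrences <- function(points) {
  if (nrow(points) < 1L) stop_("no occurrence points")
  lon <- points$lon
  lat <- points$lat
  if (any(!is.finite(lon)) || any(!is.finite(lat)) ||
      any(lon < -180 | lon > 180) || any(lat < -90 | lat > 90))
    stop_("coordinates must be finite, lon in [-180, 180], lat in [-90, 90]")
  # unwrap across the antimeridian: if the raw span exceeds 180 degrees,
  # shift western longitudes by +360 so the cloud is contiguous
  if (diff(range(lon)) > 180) lon <- ifelse(lon < 0, lon + 360, lon)
  lon0 <- mean(lon)
  lat_ts <- mean(lat)
  k <- cos(lat_ts * pi / 180)
  x <- EARTH_RADIUS_KM * (lon - lon0) * pi / 180 * k
  y <- EARTH_RADIUS_KM * sin(lat * pi / 180) / k
  structure(cbind(x = x, y = y), lon0 = lon0, lat_ts = lat_ts)
}

#' Extent of occurrence (EOO)
#'
#' Area of the planar convex hull of the projected occurrences. Fewer than
#' three distinct non-collinear points give an EOO of 0 km2 (hull areas
#' below 1e-6 km2 are reported as 0).
#'
#' @inheritParams project_occurrences
#' @return EOO in km2.
#' @export
eoo <- function(points) {
  xy <- project_occurrences(points)
  xy <- unique(xy)
  if (nrow(xy) < 3L) return(0)
  h <- chull(xy[, 1], xy[, 2])
  a <- polygon_area(xy[h, 1], xy[h, 2])
  if (a < 1e-6) 0 else a
}

#' Area of occupancy (AOO)
#'
#' Number of occupied cells of a fixed grid (edge `cell_km`, anchored at the
#' projection origin) times the cell area. The default 2-km grid gives the
#' IUCN-standard AOO.
#'
#' @inheritParams project_occurrences
#' @param cell_km grid cell edge in km (default 2).
#' @param shift_search if a positive integer `s`, additionally minimises the
#'   occupied-cell count over an `s` x `s` lattice of sub-cell grid-origin
#'   shifts and reports that minimum (the default 0 keeps the deterministic
#'   anchored grid).
#' @return List: `aoo_km2`, `n_occupied_cells`, `cell_km`.
#' @export
aoo <- function(points, cell_km = 2, shift_search = 0L) {
  assert_scalar_number(cell_km, "cell_km", 1e-9)
  xy <- project_occurrences(points)
  count_cells <- function(dx, dy) {
    cells <- paste(floor((xy[, 1] - dx) / cell_km),
                   floor((xy[, 2] - dy) / cell_km))
    length(unique(cells))
  }
  n <- count_cells(0, 0)
  if (shift_search >= 1L) {
    s <- as.integer(shift_search)
    offs <- (seq_len(s) - 1L) / s * cell_km
    for (dx in offs) for (dy in offs) n <- min(n, count_cells(dx, dy))
  }
  list(aoo_km2 = n * cell_km^2, n_occupied_cells = n, cell_km = cell_km)
}

#' IUCN criterion-B2 category from the AOO
#'
#' Applies the B2 area thresholds only: CR below 10 km2, EN below 500 km2,
#' VU below 2000 km2, otherwise NT-or-LC. The B2 sub-conditions
#' (fragmentation, continuing decline, extreme fluctuation) are NOT
#' evaluated, so the result is a threshold category suggestion, not a Red
#' List assessment; `caveat` records this.
#'
#' @param aoo_km2 area of occupancy in km2.
#' @return List: `category` (one of `"CR"`, `"EN"`, `"VU"`, `"NT-or-LC"`)
#'   and `caveat`.
#' @export
category_b2 <- function(aoo_km2) {
  assert_scalar_number(aoo_km2, "aoo_km2", 0)
  category <- if (aoo_km2 < 10) "CR" else if (aoo_km2 < 500) "EN"
              else if (aoo_km2 < 2000) "VU" else "NT-or-LC"
  list(category = category,
       caveat = "B2 area thresholds only; sub-conditions (fragmentation/decline/fluctuation) not evaluated")
}

#' Geographic range metrics for an occurrence set
#'
#' Computes EOO, AOO and the criterion-B2 category suggestion in one call.
#'
#' @inheritParams aoo
#' @return List of class `"range_metrics"`: `eoo_km2`, `aoo_km2`,
#'   `n_occupied_cells`, `cell_km`, `category_b2`, `caveat`, `n_points`.
#' @examples
#' occ <- sim_occurrences(1, spread_km = 0)
#' range_metrics(occ)   # single site: EOO 0, AOO 4 km2, CR
#' @export
range_metrics <- function(points, cell_km = 2, shift_search = 0L) {
  a <- aoo(points, cell_km = cell_km, shift_search = shift_search)
  cat_b2 <- category_b2(a$aoo_km2)
  structure(list(eoo_km2 = eoo(points), aoo_km2 = a$aoo_km2,
                 n_occupied_cells = a$n_occupied_cells, cell_km = a$cell_km,
                 category_b2 = cat_b2$category, caveat = cat_b2$caveat,
                 n_points = nrow(points)),
            class = "range_metrics")
}

#' @export
print.range_metrics <- function(x, ...) {
  cat(sprintf(paste0("range metrics (%d occurrence records)\n",
                     "  EOO: %.2f km2\n",
                     "  AOO: %.0f km2 (%d cells of %g km)\n",
                     "  B2 threshold category: %s\n  note: %s\n"),
              x$n_points, x$eoo_km2, x$aoo_km2, x$n_occupied_cells,
              x$cell_km, x$category_b2, x$caveat))
  invisible(x)
}
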