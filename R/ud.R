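#' Mean per-trip maximum foraging range
#'
#' Great-circle (haversine) distance from the colony to each fix; the
#' foraging range of a trip is its maximum, and the summary is the
#' arithmetic mean over trips.
#'
#' @param fixes data.frame with `lon`, `lat` and a `trip_id` column.
#' @param colony named numeric `c(lon, lat)`.
#' @return mean per-trip maximum colony distance, km.
#' @export
foraging_range <- function(fixes, colony) {
  if (nrow(fixes) == 0L) stop("no fixes")
  if (!"trip_id" %in% names(fixes)) stop("fixes need a trip_id column")
  d <- geosphere::distHaversine(c(colony[["lon"]], colony[["lat"]]),
                                cbind(fixes$lon, fixes$lat)) / 1000
  mean(tapply(d, fixes$trip_id, max))
}

#' Kernel smoothing scale from the mean foraging range
#'
#' `h = factor * log(mean_range_km)`; with the defaults (natural log,
#' factor 2) a ~55 km mean range gives h close to 8 km.
#'
#' @param mean_range_km mean per-trip maximum foraging range, km (> 1).
#' @param factor multiplier applied to the log range (default 2).
#' @param base logarithm base (default `exp(1)`).
#' @return bandwidth h in km.
#' @export
smoothing_scale <- function(mean_range_km, factor = 2, base = exp(1)) {
  if (!is.numeric(mean_range_km) || mean_range_km <= 1)
    stop("mean foraging range must exceed 1 km (log would be non-positive)")
  factor * log(mean_range_km, base = base)
}

#' Project lon/lat to an azimuthal-equidistant plane about the colony
#'
#' x/y in km; distances from the central point (the colony) are preserved,
#' which is the property that matters for a central-place forager.
#'
#' @param lon,lat coordinates, decimal degrees.
#' @param colony named numeric `c(lon, lat)`.
#' @return two-column matrix `x`, `y` in km.
#' @export
project_aeqd <- function(lon, lat, colony) {
  p0 <- c(colony[["lon"]], colony[["lat"]])
  d <- geosphere::distHaversine(p0, cbind(lon, lat)) / 1000
  b <- geosphere::bearing(p0, cbind(lon, lat)) * pi / 180
  b[is.na(b)] <- 0                      # point exactly at the colony
  cbind(x = d * sin(b), y = d * cos(b))
}

#' Kernel density utilization distribution of dive locations
#'
#' Isotropic bivariate Gaussian kernel density on a regular km grid in the
#' azimuthal-equidistant plane centred on the colony. The grid pads the
#' point extent by at least `3 h` on every side and the surface is
#' normalized to unit mass (sum of cell density times cell area = 1).
#'
#' @param lon,lat dive locations, decimal degrees (at least one point).
#' @param colony named numeric `c(lon, lat)`.
#' @param h kernel bandwidth, km (> 0), applied on both axes.
#' @param cell_km grid cell size, km (default 1).
#' @param pad padding beyond the point extent in multiples of h (default 3).
#' @return object of class `ud_grid`: `x`, `y` (cell-centre coordinates,
#'   km), `density` (matrix, rows = y, cols = x, per km^2), `h`, `cell_km`,
#'   `colony`.
#' @export
kde_ud <- function(lon, lat, colony, h, cell_km = 1, pad = 3) {
  ok <- !is.na(lon) & !is.na(lat)
  lon <- lon[ok]; lat <- lat[ok]
  if (length(lon) == 0L) stop("no points")
  if (!is.numeric(h) || h <= 0) stop("h must be > 0")
  xy <- project_aeqd(lon, lat, colony)
  xr <- range(xy[, 1]) + c(-1, 1) * pad * h
  yr <- range(xy[, 2]) + c(-1, 1) * pad * h
  xc <- seq(xr[1] + cell_km / 2, xr[2], by = cell_km)
  yc <- seq(yr[1] + cell_km / 2, yr[2], by = cell_km)
  # separable Gaussian: density = (Ky %*% t(Kx)) / n
  Kx <- outer(xy[, 1], xc, function(p, g) stats::dnorm(g - p, sd = h))
  Ky <- outer(xy[, 2], yc, function(p, g) stats::dnorm(g - p, sd = h))
  dens <- crossprod(Ky, Kx) / nrow(xy)        # rows = y, cols = x
  dens <- dens / (sum(dens) * cell_km^2)      # renormalize truncation loss
  structure(list(x = xc, y = yc, density = dens, h = h, cell_km = cell_km,
                 colony = colony),
            class = "ud_grid")
}

#' @export
print.ud_grid <- function(x, ...) {
  cat(sprintf("ud_grid: %d x %d cells of %g km, h = %g km, mass = %.6f\n",
              length(x$y), length(x$x), x$cell_km, x$h,
              sum(x$density) * x$cell_km^2))
  invisible(x)
}

#' @export
plot.ud_grid <- function(x, levels = c(0.5, 0.95), ...) {
  graphics::image(x$x, x$y, t(x$density), xlab = "x (km east)",
                  ylab = "y (km north)", col = grDevices::hcl.colors(64), ...)
  for (p in levels) {
    m <- isopleth(x, p)
    graphics::contour(x$x, x$y, t(m * 1), levels = 0.5, add = TRUE,
                      drawlabels = FALSE)
  }
  graphics::points(0, 0, pch = 18, cex = 1.4)
  invisible(x)
}

#' Isopleth mask of a utilization distribution
#'
#' The smallest set of highest-density cells whose summed mass is at least
#' `p`. Masks are nested: the 50% region is contained in the 95% region.
#'
#' @param ud a `ud_grid`.
#' @param p probability level in (0, 1).
#' @return logical matrix (same shape as `ud$density`), TRUE for cells in
#'   the isopleth region.
#' @export
isopleth <- function(ud, p) {
  stopifnot(inherits(ud, "ud_grid"), p > 0, p < 1)
  mass <- ud$density * ud$cell_km^2
  o <- order(mass, decreasing = TRUE)
  cum <- cumsum(mass[o])
  k <- which(cum >= p)[1]
  m <- matrix(FALSE, nrow(mass), ncol(mass))
  m[o[seq_len(k)]] <- TRUE
  m
}

#' Fraction of points falling inside an isopleth mask
#'
#' @param ud a `ud_grid`.
#' @param mask logical mask from [isopleth()].
#' @param lon,lat test points, decimal degrees.
#' @return proportion of the points inside masked cells (points off the
#'   grid count as outside).
#' @export
isopleth_coverage <- function(ud, mask, lon, lat) {
  xy <- project_aeqd(lon, lat, ud$colony)
  ci <- findInterval(xy[, 1], ud$x - ud$cell_km / 2)
  ri <- findInterval(xy[, 2], ud$y - ud$cell_km / 2)
  inside <- ci >= 1 & ci <= length(ud$x) & ri >= 1 & ri <= length(ud$y)
  hit <- logical(length(lon))
  hit[inside] <- mask[cbind(ri[inside], ci[inside])]
  mean(hit)
}

#' Export an isopleth mask as GeoJSON cell polygons
#'
#' Writes the masked cells as a MultiPolygon of cell squares back-projected
#' to lon/lat (WGS84) — a presentation artifact; analysis uses the mask.
#'
#' @param ud a `ud_grid`.
#' @param mask logical mask from [isopleth()].
#' @param path output path; `level` is stored as a property.
#' @param level probability level recorded in the feature properties.
#' @return `path`, invisibly.
#' @export
write_isopleth_geojson <- function(ud, mask, path, level = NA_real_) {
  unproject <- function(x, y) {
    d <- sqrt(x^2 + y^2) * 1000
    b <- atan2(x, y) * 180 / pi
    p <- geosphere::destPoint(c(ud$colony[["lon"]], ud$colony[["lat"]]), b, d)
    p[d == 0, 1] <- ud$colony[["lon"]]; p[d == 0, 2] <- ud$colony[["lat"]]
    p
  }
  idx <- which(mask, arr.ind = TRUE)
  half <- ud$cell_km / 2
  polys <- lapply(seq_len(nrow(idx)), function(i) {
    cx <- ud$x[idx[i, 2]]; cy <- ud$y[idx[i, 1]]
    corner_x <- c(cx - half, cx + half, cx + half, cx - half, cx - half)
    corner_y <- c(cy - half, cy - half, cy + half, cy + half, cy - half)
    ll <- unproject(corner_x, corner_y)
    list(lapply(seq_len(5), function(k) c(ll[k, 1], ll[k, 2])))
  })
  gj <- list(type = "FeatureCollection", features = list(list(
    type = "Feature", properties = list(level = level),
    geometry = list(type = "MultiPolygon", coordinates = polys))))
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = 8)
  invisible(path)
}
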