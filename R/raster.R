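#' Lightweight lon/lat raster grid
#'
#' A minimal raster container used throughout the package: a numeric matrix of
#' cell values on a regular lon/lat (EPSG:4326) grid, with rows running
#' south to north and columns west to east. Cell centres are at
#' `xmin + (col - 0.5) * cell` and `ymin + (row - 0.5) * cell`.
#'
#' @param values numeric matrix, `nrow` = number of latitude rows (south to
#'   north), `ncol` = number of longitude columns (west to east).
#' @param xmin,ymin western / southern edge of the grid, decimal degrees.
#' @param cell cell size in decimal degrees (> 0).
#' @return an object of class `grid_raster`.
#' @export
grid_raster <- function(values, xmin, ymin, cell) {
  stopifnot(is.matrix(values), is.numeric(cell), cell > 0)
  structure(list(values = values, xmin = xmin, ymin = ymin, cell = cell),
            class = "grid_raster")
}

#' @export
print.grid_raster <- function(x, ...) {
  v <- x$values
  cat(sprintf("grid_raster: %d rows x %d cols, cell %g deg\n",
              nrow(v), ncol(v), x$cell))
  cat(sprintf("  lon [%g, %g], lat [%g, %g]\n",
              x$xmin, x$xmin + ncol(v) * x$cell,
              x$ymin, x$ymin + nrow(v) * x$cell))
  rng <- range(v, na.rm = TRUE)
  cat(sprintf("  values [%g, %g], %d NA cells\n", rng[1], rng[2], sum(is.na(v))))
  invisible(x)
}

#' Cell-centre coordinates of a grid raster
#' @param r a `grid_raster`.
#' @return numeric vector of longitudes (`gr_xcoords`) or latitudes
#'   (`gr_ycoords`) of cell centres.
#' @export
gr_xcoords <- function(r) r$xmin + (seq_len(ncol(r$values)) - 0.5) * r$cell

#' @rdname gr_xcoords
#' @export
gr_ycoords <- function(r) r$ymin + (seq_len(nrow(r$values)) - 0.5) * r$cell

#' Row/column index of the cell containing each point
#'
#' Points on the outer boundary are assigned to the adjacent interior cell;
#' points outside the grid get NA.
#'
#' @param r a `grid_raster`.
#' @param lon,lat point coordinates, decimal degrees.
#' @return integer matrix with columns `row`, `col`.
#' @export
gr_cell_of <- function(r, lon, lat) {
  nx <- ncol(r$values); ny <- nrow(r$values)
  col <- floor((lon - r$xmin) / r$cell) + 1L
  row <- floor((lat - r$ymin) / r$cell) + 1L
  col[lon == r$xmin + nx * r$cell] <- nx
  row[lat == r$ymin + ny * r$cell] <- ny
  bad <- col < 1L | col > nx | row < 1L | row > ny
  col[bad] <- NA_integer_; row[bad] <- NA_integer_
  cbind(row = row, col = col)
}

#' Extract raster values at point locations
#'
#' Nearest-cell (cell containing the point) lookup; no interpolation.
#'
#' @inheritParams gr_cell_of
#' @return numeric vector of cell values; NA outside the grid or on NA cells.
#' @export
gr_extract <- function(r, lon, lat) {
  rc <- gr_cell_of(r, lon, lat)
  out <- rep(NA_real_, length(lon))
  ok <- !is.na(rc[, 1])
  out[ok] <- r$values[cbind(rc[ok, 1], rc[ok, 2])]
  out
}

# metres per degree of longitude/latitude at a given latitude (spherical)
.m_per_deg <- function(lat) {
  R <- 6371008.8
  list(x = pi / 180 * R * cos(lat * pi / 180), y = pi / 180 * R)
}

#' Seafloor slope from a bathymetry raster
#'
#' Slope in degrees from finite differences of depth (m, positive down):
#' central differences on interior cells, one-sided at edges. Cell widths are
#' converted to metres per row latitude, so a planar bathymetry with gradient
#' g metres per cell of width w metres gives slope `atan(g/w)` uniformly on
#' interior cells.
#'
#' @param bathy a `grid_raster` of depth in metres (NA on land).
#' @return a `grid_raster` of slope in degrees (non-negative; NA on land).
#' @export
gr_slope <- function(bathy) {
  z <- bathy$values
  ny <- nrow(z); nx <- ncol(z)
  if (ny < 2L || nx < 2L)
    stop("slope needs a grid with at least 2 rows and 2 columns")
  lat <- gr_ycoords(bathy)
  # one-sided at the edges, central inside; NA-adjacent cells fall back or NA
  ddir <- function(m, along) {
    n <- if (along == "col") nx else ny
    g <- array(NA_real_, dim(m))
    idx <- function(i) if (along == "col") m[, i, drop = FALSE] else m[i, , drop = FALSE]
    set <- function(i, v) if (along == "col") g[, i] <<- v else g[i, ] <<- v
    for (i in seq_len(n)) {
      lo <- max(1L, i - 1L); hi <- min(n, i + 1L)
      set(i, (idx(hi) - idx(lo)) / (hi - lo))
    }
    g
  }
  gx <- ddir(z, "col")           # per cell eastward
  gy <- ddir(z, "row")           # per cell northward
  mpd <- .m_per_deg(lat)
  wx <- matrix(rep(mpd$x * bathy$cell, nx), ny, nx)   # row-wise x cell width m
  wy <- mpd$y * bathy$cell
  sl <- atan(sqrt((gx / wx)^2 + (gy / wy)^2)) * 180 / pi
  grid_raster(sl, bathy$xmin, bathy$ymin, bathy$cell)
}

#' Read and write ESRI ASCII grid rasters
#'
#' Plain-text raster interchange (`.asc`): a 6-line header (ncols, nrows,
#' xllcorner, yllcorner, cellsize, NODATA_value) followed by rows of values
#' from north to south. Coordinates are EPSG:4326 decimal degrees.
#'
#' @param r a `grid_raster`.
#' @param path file path.
#' @return `read_ascii_grid` returns a `grid_raster`; `write_ascii_grid`
#'   returns `path` invisibly.
#' @export
write_ascii_grid <- function(r, path) {
  v <- r$values
  v[is.na(v)] <- -9999
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", ncol(v)),
    sprintf("nrows %d", nrow(v)),
    sprintf("xllcorner %.10g", r$xmin),
    sprintf("yllcorner %.10g", r$ymin),
    sprintf("cellsize %.10g", r$cell),
    "NODATA_value -9999"), con)
  # ESRI order: first data row is the northernmost
  for (i in rev(seq_len(nrow(v))))
    writeLines(paste(formatC(v[i, ], format = "g", digits = 10),
                     collapse = " "), con)
  invisible(path)
}

#' @rdname write_ascii_grid
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(trimws(lines[1:6]), "\\s+")
  key <- tolower(vapply(hdr, `[`, "", 1L))
  val <- as.numeric(vapply(hdr, `[`, "", 2L))
  names(val) <- key
  ncols <- as.integer(val[["ncols"]]); nrows <- as.integer(val[["nrows"]])
  body <- scan(text = paste(lines[-(1:6)], collapse = "\n"), quiet = TRUE)
  if (length(body) != ncols * nrows)
    stop("ASCII grid body does not match header dimensions: ", path)
  m <- matrix(body, nrow = nrows, ncol = ncols, byrow = TRUE)
  m <- m[rev(seq_len(nrows)), , drop = FALSE]  # back to south-to-north rows
  m[m == val[["nodata_value"]]] <- NA_real_
  grid_raster(m, val[["xllcorner"]], val[["yllcorner"]], val[["cellsize"]])
}
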