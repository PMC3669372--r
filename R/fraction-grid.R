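# The fraction grid container: a regular grid of per-cell converted fraction.

#' Construct a fraction grid
#'
#' A `fraction_grid` holds one year of gridded converted-land fractions: a
#' numeric matrix (rows run north to south, columns west to east), a
#' geotransform (top-left origin, positive cell sizes) and a CRS tag. `NA`
#' cells are nodata (sea / unobserved) and are excluded from every area
#' denominator downstream.
#'
#' @param values numeric matrix of fractions in `[0, 1]` (or `NA`).
#' @param year integer year the grid refers to.
#' @param x0 x coordinate of the grid's left (west) edge.
#' @param y1 y coordinate of the grid's top (north) edge.
#' @param dx,dy positive cell sizes (km for `"planar_km"`, degrees for
#'   `"geographic"`).
#' @param crs `"planar_km"` or `"geographic"`.
#' @param check validate value range (set `FALSE` for integer class rasters).
#' @return an object of class `fraction_grid`.
#' @examples
#' g <- fraction_grid(matrix(runif(12), 3, 4), year = 2000, dx = 8, dy = 8)
#' g
#' @export
fraction_grid <- function(values, year, x0 = 0, y1 = nrow(values) * dy,
                          dx = 1, dy = dx, crs = "planar_km", check = TRUE) {
  stopifnot(is.matrix(values), dx > 0, dy > 0)
  if (!crs %in% c("planar_km", "geographic")) {
    rlang::abort("crs must be 'planar_km' or 'geographic'")
  }
  if (check) {
    v <- values[!is.na(values)]
    if (length(v) && (min(v) < 0 || max(v) > 1)) {
      rlang::abort("fraction values must lie in [0, 1] (or be NA for nodata)")
    }
  }
  structure(
    list(values = values, year = as.integer(year), x0 = x0, y1 = y1,
         dx = dx, dy = dy, crs = crs),
    class = "fraction_grid"
  )
}

#' @export
print.fraction_grid <- function(x, ...) {
  v <- x$values[!is.na(x$values)]
  cat(sprintf(
    "<fraction_grid> %d x %d cells (%s), year %d\n  cell %g x %g, mean fraction %.4f, %d nodata cells\n",
    nrow(x$values), ncol(x$values), x$crs, x$year, x$dx, x$dy,
    if (length(v)) mean(v) else NA_real_, sum(is.na(x$values))
  ))
  invisible(x)
}

#' @export
dim.fraction_grid <- function(x) dim(x$values)

#' Per-cell land area of a grid, in km^2
#'
#' Planar grids have constant cell area; geographic grids use the spherical
#' cos(latitude) approximation evaluated at each row's cell-centre latitude.
#' Returns a matrix congruent with the grid values; nodata cells still get an
#' area (masking is the caller's job).
#'
#' @param grid a [fraction_grid()].
#' @return numeric matrix of cell areas (km^2).
#' @export
cell_area_km2 <- function(grid) {
  nr <- nrow(grid$values); nc <- ncol(grid$values)
  if (grid$crs == "planar_km") {
    matrix(grid$dx * grid$dy, nr, nc)
  } else {
    lat <- grid$y1 - (seq_len(nr) - 0.5) * grid$dy
    a_row <- grid$dx * KM_PER_DEG_LON * cos(lat * pi / 180) * grid$dy * KM_PER_DEG_LAT
    matrix(rep(a_row, nc), nr, nc)
  }
}

#' Assemble congruent yearly grids into a land-use series
#'
#' @param grids list of [fraction_grid()] objects sharing one geotransform,
#'   CRS and nodata mask, with strictly increasing years.
#' @return an object of class `landuse_series` (a list of grids with a
#'   `years` attribute).
#' @export
landuse_series <- function(grids) {
  stopifnot(length(grids) >= 1)
  years <- vapply(grids, function(g) g$year, integer(1))
  if (any(diff(years) <= 0)) rlang::abort("series years must be strictly increasing")
  g0 <- grids[[1]]
  for (g in grids[-1]) {
    same <- identical(dim(g$values), dim(g0$values)) &&
      isTRUE(all.equal(c(g$x0, g$y1, g$dx, g$dy), c(g0$x0, g0$y1, g0$dx, g0$dy))) &&
      identical(g$crs, g0$crs)
    if (!same) rlang::abort("grids in a series must share geometry and CRS")
    if (!identical(is.na(g$values), is.na(g0$values))) {
      rlang::abort("grids in a series must share one nodata mask")
    }
  }
  structure(grids, years = years, class = "landuse_series")
}

#' @export
print.landuse_series <- function(x, ...) {
  yrs <- attr(x, "years")
  cat(sprintf("<landuse_series> %d years (%d-%d), %d x %d cells\n",
              length(yrs), min(yrs), max(yrs),
              nrow(x[[1]]$values), ncol(x[[1]]$values)))
  invisible(x)
}

#' Years covered by a land-use series
#' @param series a [landuse_series()].
#' @return integer vector of years.
#' @export
series_years <- function(series) attr(series, "years")
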