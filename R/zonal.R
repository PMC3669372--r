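# Zonal overlay: exact fractional cell coverage of protection layers on
# fraction grids, and the inside/outside and per-site converted percentages.

# accumulate exact rectangle-overlap fractions of each grid cell
rects_coverage_matrix <- function(rects, grid) {
  nr <- nrow(grid$values); nc <- ncol(grid$values)
  cov <- matrix(0, nr, nc)
  if (nrow(rects) == 0) return(cov)
  dx <- grid$dx; dy <- grid$dy; x0 <- grid$x0; y1 <- grid$y1
  for (p in seq_len(nrow(rects))) {
    xmn <- rects$xmin[p]; xmx <- rects$xmax[p]
    ymn <- rects$ymin[p]; ymx <- rects$ymax[p]
    j0 <- max(1L, floor((xmn - x0) / dx) + 1L)
    j1 <- min(nc, ceiling((xmx - x0) / dx))
    i0 <- max(1L, floor((y1 - ymx) / dy) + 1L)
    i1 <- min(nr, ceiling((y1 - ymn) / dy))
    if (j1 < j0 || i1 < i0) next
    jj <- j0:j1; ii <- i0:i1
    colov <- pmax(pmin(x0 + jj * dx, xmx) - pmax(x0 + (jj - 1) * dx, xmn), 0)
    rowov <- pmax(pmin(y1 - (ii - 1) * dy, ymx) - pmax(y1 - ii * dy, ymn), 0)
    cov[ii, jj] <- cov[ii, jj] + outer(rowov, colov) / (dx * dy)
  }
  cov
}

# cell weights of one site's rectangle, restricted to its cell window;
# returns parallel vectors of row index, column index and coverage fraction
site_cell_weights <- function(site, grid, mode) {
  nr <- nrow(grid$values); nc <- ncol(grid$values)
  dx <- grid$dx; dy <- grid$dy; x0 <- grid$x0; y1 <- grid$y1
  empty <- list(i = integer(), j = integer(), w = numeric())
  xmn <- site$xmin; xmx <- site$xmax; ymn <- site$ymin; ymx <- site$ymax
  if (mode == "fractional") {
    j0 <- max(1L, floor((xmn - x0) / dx) + 1L)
    j1 <- min(nc, ceiling((xmx - x0) / dx))
    i0 <- max(1L, floor((y1 - ymx) / dy) + 1L)
    i1 <- min(nr, ceiling((y1 - ymn) / dy))
    if (j1 < j0 || i1 < i0) return(empty)
    jj <- j0:j1; ii <- i0:i1
    colov <- pmax(pmin(x0 + jj * dx, xmx) - pmax(x0 + (jj - 1) * dx, xmn), 0)
    rowov <- pmax(pmin(y1 - (ii - 1) * dy, ymx) - pmax(y1 - ii * dy, ymn), 0)
    w <- outer(rowov, colov) / (dx * dy)
    list(i = rep(ii, times = length(jj)), j = rep(jj, each = length(ii)),
         w = as.vector(w))
  } else {
    cx <- x0 + (seq_len(nc) - 0.5) * dx
    cy <- y1 - (seq_len(nr) - 0.5) * dy
    jj <- which(cx >= xmn & cx < xmx)
    ii <- which(cy >= ymn & cy < ymx)
    if (!length(ii) || !length(jj)) return(empty)
    list(i = rep(ii, times = length(jj)), j = rep(jj, each = length(ii)),
         w = rep(1, length(ii) * length(jj)))
  }
}

# cell-centre membership: 1 where the cell centre lies inside any rectangle
rects_centre_matrix <- function(rects, grid) {
  nr <- nrow(grid$values); nc <- ncol(grid$values)
  cov <- matrix(0, nr, nc)
  if (nrow(rects) == 0) return(cov)
  cx <- grid$x0 + (seq_len(nc) - 0.5) * grid$dx
  cy <- grid$y1 - (seq_len(nr) - 0.5) * grid$dy
  for (p in seq_len(nrow(rects))) {
    jj <- which(cx >= rects$xmin[p] & cx < rects$xmax[p])
    ii <- which(cy >= rects$ymin[p] & cy < rects$ymax[p])
    if (length(ii) && length(jj)) cov[ii, jj] <- 1
  }
  cov
}

#' Coverage field of a protection layer on a grid
#'
#' Per cell, the fraction of the cell's area lying inside the layer. In
#' `"fractional"` mode (the default) this is the exact polygon-by-cell
#' intersection area divided by the cell area, so
#' `sum(coverage * cell_area)` equals the layer area exactly. The
#' `"cell_centre"` mode instead marks whole cells by centre membership, the
#' coarser convention some overlay workflows use; it is provided for
#' comparison.
#'
#' @param layer a [merge_layer()] result.
#' @param grid a [fraction_grid()] sharing the layer's CRS.
#' @param mode `"fractional"` or `"cell_centre"`.
#' @return numeric matrix in `[0, 1]`, congruent with `grid$values`.
#' @export
coverage <- function(layer, grid, mode = c("fractional", "cell_centre")) {
  mode <- rlang::arg_match(mode)
  if (!identical(layer$crs, grid$crs)) {
    rlang::abort(paste0("CRS mismatch: layer is ", layer$crs, ", grid is ", grid$crs))
  }
  if (mode == "fractional") {
    cov <- rects_coverage_matrix(layer$parts, grid)
    # layer parts are disjoint so cov <= 1 up to float error
    pmin(cov, 1)
  } else {
    rects_centre_matrix(layer$parts, grid)
  }
}

#' Inside/outside converted percentages for one year
#'
#' Area-weighted converted percentages inside and outside a coverage field:
#' `pct_inside = 100 * sum(f * cov * a) / sum(cov * a)` over data cells in the
#' region, and analogously with `1 - cov` for outside. Nodata cells and cells
#' outside the region mask enter neither numerator nor denominator. An empty
#' zone yields an `NA` percentage with the corresponding `*_defined` flag set
#' to `FALSE` (never silently 0).
#'
#' @param grid a [fraction_grid()].
#' @param cov coverage matrix from [coverage()].
#' @param region_mask logical matrix of cells in the analysis region
#'   (default: all data cells).
#' @return one-row tibble: `year`, `pct_converted_inside`,
#'   `pct_converted_outside`, `area_inside_km2`, `area_outside_km2`,
#'   `inside_defined`, `outside_defined`.
#' @export
zonal_summary <- function(grid, cov, region_mask = NULL) {
  v <- grid$values
  if (!identical(dim(cov), dim(v))) rlang::abort("coverage not congruent with grid")
  if (is.null(region_mask)) region_mask <- matrix(TRUE, nrow(v), ncol(v))
  if (!identical(dim(region_mask), dim(v))) rlang::abort("region mask not congruent with grid")
  a <- cell_area_km2(grid)
  use <- region_mask & !is.na(v)
  ain <- sum(cov[use] * a[use])
  aout <- sum((1 - cov[use]) * a[use])
  pin <- if (ain > 0) 100 * sum(v[use] * cov[use] * a[use]) / ain else NA_real_
  pout <- if (aout > 0) 100 * sum(v[use] * (1 - cov[use]) * a[use]) / aout else NA_real_
  tibble::tibble(
    year = grid$year,
    pct_converted_inside = pin,
    pct_converted_outside = pout,
    area_inside_km2 = ain,
    area_outside_km2 = aout,
    inside_defined = ain > 0,
    outside_defined = aout > 0
  )
}

#' Converted percentage within each individual site
#'
#' Uses each site's own footprint (not the merged estate), so overlapping
#' sites each count the shared cells: this matches using individual protected
#' areas as analysis units. Sites whose footprint intersects no land cell are
#' flagged and get `NA`.
#'
#' @param sites register tibble of polygon records.
#' @param grid a [fraction_grid()].
#' @param region_mask optional logical matrix restricting the analysis region.
#' @param mode coverage mode, as in [coverage()].
#' @return tibble: `site_id`, `year`, `pct_converted`, `area_km2` (land area
#'   intersected), `defined`.
#' @export
per_site_summary <- function(sites, grid, region_mask = NULL,
                             mode = c("fractional", "cell_centre")) {
  mode <- rlang::arg_match(mode)
  traj <- per_site_trajectory(sites, landuse_series(list(grid)),
                              region_mask = region_mask, mode = mode)
  traj
}

#' Per-site converted-percentage trajectories
#'
#' The decadal percent-converted series within each site's own footprint.
#' Site coverage is time-invariant, so the coverage weights are computed once
#' per site and reused across years.
#'
#' @param sites register tibble of polygon records.
#' @param series a [landuse_series()].
#' @param region_mask optional logical matrix.
#' @param mode coverage mode, as in [coverage()].
#' @return tibble: `site_id`, `year`, `pct_converted`, `area_km2`, `defined`.
#' @export
per_site_trajectory <- function(sites, series, region_mask = NULL,
                                mode = c("fractional", "cell_centre")) {
  mode <- rlang::arg_match(mode)
  validate_register(sites)
  if (any(sites$geom_type != "polygon")) {
    rlang::abort("per-site statistics need polygon records; filter the register first")
  }
  g0 <- series[[1]]
  if (is.null(region_mask)) region_mask <- matrix(TRUE, nrow(g0$values), ncol(g0$values))
  years <- series_years(series)
  vals <- lapply(series, function(g) g$values)
  a <- cell_area_km2(g0)

  # per-site coverage restricted to the site's cell window (sites are small
  # relative to the grid, so this avoids touching the full grid per site)
  n_sites <- nrow(sites)
  n_years <- length(years)
  pct <- matrix(NA_real_, n_years, n_sites)
  den_all <- numeric(n_sites)
  for (s in seq_len(n_sites)) {
    win <- site_cell_weights(sites[s, ], g0, mode)
    if (!length(win$i)) next
    cells <- cbind(win$i, win$j)
    ok <- region_mask[cells] & !is.na(vals[[1]][cells]) & win$w > 0
    w <- win$w[ok] * a[cells][ok]
    cells <- cells[ok, , drop = FALSE]
    den <- sum(w)
    den_all[s] <- den
    if (den > 0) {
      pct[, s] <- vapply(vals, function(v) 100 * sum(v[cells] * w) / den,
                         numeric(1))
    }
  }
  tibble::tibble(
    site_id = rep(sites$site_id, each = n_years),
    year = rep(years, times = n_sites),
    pct_converted = as.vector(pct),
    area_km2 = rep(den_all, each = n_years),
    defined = rep(den_all > 0, each = n_years)
  )
}

#' Decadal inside/outside conversion trajectory
#'
#' Overlays each decade's fraction grid on the protection layer as the estate
#' existed in that decade (inner join of layer reference years and series
#' years) and returns one [zonal_summary()] row per matched year. Years before
#' the first establishment have an empty estate and an undefined inside
#' percentage.
#'
#' @param layers list of [merge_layer()] layers (e.g. [historical_layers()]).
#' @param series a [landuse_series()].
#' @param region_mask optional logical matrix.
#' @param mode coverage mode, as in [coverage()].
#' @return tibble of zonal summaries, one row per matched year.
#' @export
trajectory <- function(layers, series, region_mask = NULL,
                       mode = c("fractional", "cell_centre")) {
  mode <- rlang::arg_match(mode)
  layer_years <- vapply(layers, function(l) l$reference_year, integer(1))
  years <- series_years(series)
  common <- intersect(layer_years, years)
  if (!length(common)) rlang::abort("no overlap between layer years and series years")
  rows <- purrr::map(sort(common), function(y) {
    lay <- layers[[match(y, layer_years)]]
    grd <- series[[match(y, years)]]
    cov <- coverage(lay, grd, mode = mode)
    zonal_summary(grd, cov, region_mask)
  })
  dplyr::bind_rows(rows)
}
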