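# Independent oracles used across the suite. These deliberately avoid the
# package's slab-decomposition / coverage code paths: cell coverage comes from
# inclusion-exclusion over analytic rectangle intersections, and zonal
# statistics from a plain per-cell enumeration.

# area of the intersection of a set of rectangles with a cell, all axis-aligned
rects_intersection_area <- function(xmin, xmax, ymin, ymax) {
  w <- min(xmax) - max(xmin)
  h <- min(ymax) - max(ymin)
  if (w <= 0 || h <= 0) 0 else w * h
}

# union coverage fraction of one grid cell by a set of rectangles,
# via inclusion-exclusion over all non-empty subsets
oracle_cell_coverage <- function(rects, cx0, cx1, cy0, cy1) {
  touch <- which(rects$xmin < cx1 & rects$xmax > cx0 &
                   rects$ymin < cy1 & rects$ymax > cy0)
  k <- length(touch)
  if (k == 0) return(0)
  total <- 0
  for (bits in seq_len(2^k - 1)) {
    idx <- touch[bitwAnd(bits, 2^(seq_len(k) - 1)) > 0]
    a <- rects_intersection_area(
      c(rects$xmin[idx], cx0), c(rects$xmax[idx], cx1),
      c(rects$ymin[idx], cy0), c(rects$ymax[idx], cy1)
    )
    total <- total + (-1)^(length(idx) + 1) * a
  }
  total / ((cx1 - cx0) * (cy1 - cy0))
}

# full-grid union coverage matrix by per-cell inclusion-exclusion
oracle_coverage_matrix <- function(rects, grid) {
  nr <- nrow(grid$values); nc <- ncol(grid$values)
  cov <- matrix(0, nr, nc)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      cx0 <- grid$x0 + (j - 1) * grid$dx; cx1 <- cx0 + grid$dx
      cy1 <- grid$y1 - (i - 1) * grid$dy; cy0 <- cy1 - grid$dy
      cov[i, j] <- oracle_cell_coverage(rects, cx0, cx1, cy0, cy1)
    }
  }
  cov
}

# inside/outside/per-site percentages by brute-force per-cell enumeration
oracle_zonal <- function(grid, rects) {
  cov <- oracle_coverage_matrix(rects, grid)
  a <- cell_area_km2(grid)
  v <- grid$values
  ok <- !is.na(v)
  ain <- sum(cov[ok] * a[ok]); aout <- sum((1 - cov[ok]) * a[ok])
  list(
    pct_inside = 100 * sum(v[ok] * cov[ok] * a[ok]) / ain,
    pct_outside = 100 * sum(v[ok] * (1 - cov[ok]) * a[ok]) / aout,
    area_inside = ain, area_outside = aout
  )
}

oracle_site_pct <- function(rect, grid) {
  cov <- oracle_coverage_matrix(rect, grid)
  a <- cell_area_km2(grid)
  v <- grid$values
  ok <- !is.na(v) & cov > 0
  100 * sum(v[ok] * cov[ok] * a[ok]) / sum(cov[ok] * a[ok])
}

# independent scalar re-implementation of the landscape update rule,
# consuming the RNG in the same order as simulate_landscape
oracle_replay_landscape <- function(config, sites) {
  nr <- config$grid_rows; nc <- config$grid_cols; m <- config$parcels_per_cell
  cs <- config$cell_size_km
  height <- nr * cs
  acc <- matrix(NA_real_, nr, nc)
  for (j in seq_len(nc)) {
    acc[, j] <- exp(config$accessibility_gradient * ((j - 0.5) / nc - 0.5))
  }
  years <- config$years
  est_dec <- establishment_decade(sites$establishment_year, years)
  conv <- matrix(0L, nr, nc)
  out <- list(conv / m)
  set.seed(config$seed + 2L)
  for (k in seq_along(years)[-1]) {
    f <- conv / m
    h <- matrix(NA_real_, nr, nc)
    for (i in seq_len(nr)) {
      for (j in seq_len(nc)) {
        nb <- c()
        if (i > 1) nb <- c(nb, f[i - 1, j])
        if (i < nr) nb <- c(nb, f[i + 1, j])
        if (j > 1) nb <- c(nb, f[i, j - 1])
        if (j < nc) nb <- c(nb, f[i, j + 1])
        h[i, j] <- config$base_hazard *
          (1 + config$contagion_weight * mean(nb)) * acc[i, j]
        cxij <- (j - 0.5) * cs
        cyij <- height - (i - 0.5) * cs
        inside <- any(!is.na(est_dec) & est_dec <= years[k - 1] &
                        sites$geom_type == "polygon" &
                        sites$xmin <= cxij & cxij < sites$xmax &
                        sites$ymin <= cyij & cyij < sites$ymax)
        if (inside) h[i, j] <- h[i, j] * config$protection_multiplier
      }
    }
    h <- pmin(h, 1)
    draws <- stats::rbinom(nr * nc, size = m - as.vector(conv),
                           prob = as.vector(h))
    conv <- conv + matrix(draws, nr, nc)
    out[[k]] <- conv / m
  }
  out
}

# textbook paired t oracle
oracle_paired_t <- function(pre, post) {
  d <- pre - post
  n <- length(d)
  tstat <- mean(d) / (stats::sd(d) / sqrt(n))
  list(t = tstat, df = n - 1,
       p = 2 * stats::pt(abs(tstat), n - 1, lower.tail = FALSE))
}

# random rectangular sites fully inside a planar grid
random_sites <- function(n, grid, min_side = 0.5, max_side = NULL,
                         prefix = "s") {
  w <- ncol(grid$values) * grid$dx
  h <- nrow(grid$values) * grid$dy
  if (is.null(max_side)) max_side <- min(w, h) / 3
  sw <- runif(n, min_side, max_side)
  sh <- runif(n, min_side, max_side)
  x <- runif(n, 0, w - sw)
  y <- runif(n, 0, h - sh)
  pa_register(
    site_id = sprintf("%s%03d", prefix, seq_len(n)),
    xmin = x, xmax = x + sw, ymin = y, ymax = y + sh,
    iucn_category = sample(c("Ia", "II", "IV"), n, replace = TRUE),
    establishment_year = sample(1860:1990, n, replace = TRUE)
  )
}

random_grid <- function(nr, nc, year = 2000, dx = 1, na_frac = 0) {
  v <- matrix(runif(nr * nc), nr, nc)
  if (na_frac > 0) v[sample(length(v), round(na_frac * length(v)))] <- NA
  fraction_grid(v, year, dx = dx)
}
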