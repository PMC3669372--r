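# Exact geometry for axis-aligned rectangles.
#
# All polygon geometry in this package is restricted to axis-aligned
# rectangles (plus point records, which carry no footprint). This keeps every
# union, intersection and cell-coverage area analytic and exact, which is what
# makes the brute-force zonal oracles in the test suite meaningful.

KM_PER_DEG_LAT <- 110.574
KM_PER_DEG_LON <- 111.320

#' Area of axis-aligned rectangles
#'
#' For a planar CRS coordinates are kilometres and the area is exact. For a
#' geographic CRS coordinates are degrees (x = longitude, y = latitude) and
#' the area uses the spherical approximation
#' `dx * dy * 111.320 * cos(lat_mid) * 110.574` km^2.
#'
#' @param xmin,xmax,ymin,ymax rectangle bounds (km or degrees).
#' @param crs `"planar_km"` or `"geographic"`.
#' @return numeric vector of areas in km^2.
#' @keywords internal
#' @noRd
rect_area_km2 <- function(xmin, xmax, ymin, ymax, crs = "planar_km") {
  w <- pmax(xmax - xmin, 0)
  h <- pmax(ymax - ymin, 0)
  if (identical(crs, "planar_km")) {
    w * h
  } else if (identical(crs, "geographic")) {
    lat_mid <- (ymin + ymax) / 2
    w * KM_PER_DEG_LON * cos(lat_mid * pi / 180) * h * KM_PER_DEG_LAT
  } else {
    rlang::abort(paste0("unknown CRS '", crs, "'"))
  }
}

#' Decompose a set of rectangles into disjoint covered boxes
#'
#' Slab-sweep decomposition: the x and y break coordinates of all input
#' rectangles induce a grid of elementary boxes; each box is either fully
#' inside or fully outside every rectangle. Covered boxes are returned, merged
#' vertically within each x-slab where contiguous and of equal category, each
#' tagged with the strictest (lowest rank) category among the rectangles
#' covering it.
#'
#' @param rects data frame with `xmin`, `xmax`, `ymin`, `ymax`.
#' @param cat_rank integer strictness rank per rectangle (lower = stricter);
#'   if `NULL` all parts get rank 1.
#' @return tibble of disjoint parts: `xmin`, `xmax`, `ymin`, `ymax`,
#'   `cat_rank`.
#' @keywords internal
#' @noRd
decompose_rects <- function(rects, cat_rank = NULL) {
  empty <- tibble::tibble(
    xmin = numeric(), xmax = numeric(),
    ymin = numeric(), ymax = numeric(), cat_rank = integer()
  )
  n <- nrow(rects)
  if (n == 0L) return(empty)
  keep <- rects$xmax > rects$xmin & rects$ymax > rects$ymin
  rects <- rects[keep, , drop = FALSE]
  if (!is.null(cat_rank)) cat_rank <- cat_rank[keep]
  n <- nrow(rects)
  if (n == 0L) return(empty)
  if (is.null(cat_rank)) cat_rank <- rep(1L, n)

  xs <- sort(unique(c(rects$xmin, rects$xmax)))
  ys <- sort(unique(c(rects$ymin, rects$ymax)))
  nx <- length(xs) - 1L
  ny <- length(ys) - 1L

  # slab s is inside rect r iff the rect spans the whole slab
  xcov <- outer(xs[-length(xs)], rects$xmin, `>=`) & outer(xs[-1], rects$xmax, `<=`)
  ycov <- outer(ys[-length(ys)], rects$ymin, `>=`) & outer(ys[-1], rects$ymax, `<=`)

  # boxes indexed (x-slab i, y-slab j), row index b = (j-1)*nx + i
  box_cov <- xcov[rep(seq_len(nx), times = ny), , drop = FALSE] &
    ycov[rep(seq_len(ny), each = nx), , drop = FALSE]
  covered <- rowSums(box_cov) > 0
  if (!any(covered)) return(empty)

  # strictest category per covered box
  cols <- lapply(seq_len(n), function(r) {
    ifelse(box_cov[covered, r], cat_rank[r], NA_integer_)
  })
  best <- do.call(pmin, c(cols, list(na.rm = TRUE)))

  ib <- rep(seq_len(nx), times = ny)[covered]
  jb <- rep(seq_len(ny), each = nx)[covered]

  # merge contiguous same-category boxes within each x-slab
  o <- order(ib, jb)
  ib <- ib[o]; jb <- jb[o]; best <- best[o]
  m <- length(ib)
  new_grp <- c(TRUE, ib[-1] != ib[-m] | jb[-1] != jb[-m] + 1L | best[-1] != best[-m])
  grp <- cumsum(new_grp)
  j_last <- jb[c(new_grp[-1], TRUE)]
  tibble::tibble(
    xmin = xs[ib[new_grp]],
    xmax = xs[ib[new_grp] + 1L],
    ymin = ys[jb[new_grp]],
    ymax = ys[j_last + 1L],
    cat_rank = best[new_grp]
  )
}

#' Union area of axis-aligned rectangles (overlaps counted once)
#' @keywords internal
#' @noRd
rect_union_area_km2 <- function(rects, crs = "planar_km") {
  parts <- decompose_rects(rects)
  sum(rect_area_km2(parts$xmin, parts$xmax, parts$ymin, parts$ymax, crs))
}
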