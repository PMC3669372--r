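# Land-cover handling: categorical class rasters are reduced to binary
# converted/natural grids via a class map; fraction rasters (per-cell percent
# of land anthropogenically transformed, HYDE-style) pass through after unit
# scaling.

#' Load a converted/natural class map
#'
#' Class maps translate integer land-cover codes into a binary
#' converted/natural status. Maps for the GlobCover legend (codes 11, 14, 20,
#' 30 and 190 converted) and the GLC2000 legend (codes 16-18 and 22 converted)
#' ship with the package; a user CSV with columns `code,label,status` can be
#' supplied instead.
#'
#' @param dataset `"globcover"`, `"glc2000"`, or a path to a CSV file.
#' @return tibble with columns `code` (integer), `label`, `status`
#'   (`"converted"` or `"natural"`), plus a `dataset_name` attribute.
#' @examples
#' load_class_map("glc2000")
#' @export
load_class_map <- function(dataset) {
  path <- if (file.exists(dataset)) {
    dataset
  } else {
    p <- system.file("extdata", paste0("classmap_", dataset, ".csv"),
                     package = "paestate")
    if (!nzchar(p)) rlang::abort(paste0("unknown class map '", dataset, "'"))
    p
  }
  cm <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  if (!all(c("code", "label", "status") %in% names(cm))) {
    rlang::abort("class map must have columns code, label, status")
  }
  if (anyDuplicated(cm$code)) rlang::abort("class map codes must be unique")
  if (!all(cm$status %in% c("converted", "natural"))) {
    rlang::abort("class map status must be 'converted' or 'natural'")
  }
  cm$code <- as.integer(cm$code)
  attr(cm, "dataset_name") <- dataset
  cm
}

#' Reclassify a categorical land-cover raster to a binary fraction grid
#'
#' Converted codes become 1, natural codes 0; nodata is preserved. Codes absent
#' from the map default to natural (conservative: unknown classes never count
#' as converted) unless `strict = TRUE`, in which case they error.
#'
#' @param raster a [fraction_grid()] whose `values` are integer class codes
#'   (build with `check = FALSE`).
#' @param class_map a [load_class_map()] tibble.
#' @param strict error on codes absent from the map instead of defaulting
#'   them to natural.
#' @return a binary [fraction_grid()].
#' @export
reclassify <- function(raster, class_map, strict = FALSE) {
  v <- raster$values
  vv <- v[!is.na(v)]
  if (length(vv) && any(vv != round(vv))) {
    rlang::abort("reclassify() needs an integer class raster; fraction rasters must not be reclassified")
  }
  converted <- class_map$code[class_map$status == "converted"]
  known <- class_map$code
  if (strict) {
    bad <- setdiff(unique(vv), known)
    if (length(bad)) {
      rlang::abort(paste0("codes not in class map: ", paste(sort(bad), collapse = ", ")))
    }
  }
  out <- ifelse(is.na(v), NA_real_, as.numeric(v %in% converted))
  out <- matrix(out, nrow(v), ncol(v))
  fraction_grid(out, raster$year, raster$x0, raster$y1, raster$dx, raster$dy,
                raster$crs)
}

#' Read an ESRI ASCII grid as a fraction grid
#'
#' @param path file path.
#' @param year year tag for the grid.
#' @param crs coordinate system of the file (`"planar_km"` or
#'   `"geographic"`).
#' @param check validate that values lie in `[0, 1]` (disable for class
#'   rasters or percent-scaled files).
#' @return a [fraction_grid()].
#' @export
read_ascii_grid <- function(path, year, crs = "geographic", check = TRUE) {
  lines <- readLines(path, n = 6L)
  kv <- lapply(strsplit(trimws(lines), "\\s+"), function(x) x)
  hdr <- list()
  n_hdr <- 0L
  for (x in kv) {
    key <- tolower(x[[1]])
    if (key %in% c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize",
                   "nodata_value")) {
      hdr[[key]] <- as.numeric(x[[2]])
      n_hdr <- n_hdr + 1L
    } else break
  }
  for (req in c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")) {
    if (is.null(hdr[[req]])) rlang::abort(paste0("ASCII grid header missing ", req))
  }
  vals <- scan(path, what = numeric(), skip = n_hdr, quiet = TRUE)
  nr <- as.integer(hdr$nrows); nc <- as.integer(hdr$ncols)
  if (length(vals) != nr * nc) rlang::abort("ASCII grid body does not match header dimensions")
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE) # rows top to bottom
  if (!is.null(hdr$nodata_value)) m[m == hdr$nodata_value] <- NA_real_
  fraction_grid(m, year,
                x0 = hdr$xllcorner, y1 = hdr$yllcorner + nr * hdr$cellsize,
                dx = hdr$cellsize, dy = hdr$cellsize, crs = crs, check = check)
}

#' Write a fraction grid as an ESRI ASCII grid
#'
#' @param grid a [fraction_grid()] with square cells.
#' @param path output file path.
#' @param nodata value written for `NA` cells (default -1).
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(grid, path, nodata = -1) {
  if (!isTRUE(all.equal(grid$dx, grid$dy))) {
    rlang::abort("ESRI ASCII grids require square cells")
  }
  nr <- nrow(grid$values); nc <- ncol(grid$values)
  hdr <- c(
    paste("ncols", nc), paste("nrows", nr),
    paste("xllcorner", format(grid$x0, digits = 15)),
    paste("yllcorner", format(grid$y1 - nr * grid$dy, digits = 15)),
    paste("cellsize", format(grid$dx, digits = 15)),
    paste("NODATA_value", nodata)
  )
  m <- grid$values
  m[is.na(m)] <- nodata
  body <- apply(m, 1, function(r) paste(format(r, digits = 10, trim = TRUE), collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Load a fraction-raster time series
#'
#' Reads one raster per year, optionally rescales percent values (0-100) to
#' fractions, validates the range and cross-year congruence, and returns a
#' [landuse_series()].
#'
#' @param paths character vector of ESRI ASCII grid paths.
#' @param years integer years matching `paths` one to one.
#' @param percent are file values percentages 0-100 (divided by 100 on load)?
#' @param crs coordinate system of the files.
#' @return a [landuse_series()].
#' @export
load_fraction_series <- function(paths, years, percent = TRUE, crs = "geographic") {
  if (length(paths) != length(years)) rlang::abort("paths and years must match 1:1")
  grids <- purrr::map2(paths, years, function(p, y) {
    g <- read_ascii_grid(p, y, crs = crs, check = FALSE)
    if (percent) g$values <- g$values / 100
    hi <- 1 + 1e-9
    bad <- which(!is.na(g$values) & (g$values < 0 | g$values > hi))
    if (length(bad)) {
      rlang::abort(paste0(
        "values outside the declared range in ", p, " at cells ",
        paste(utils::head(bad, 10), collapse = ", "),
        if (length(bad) > 10) " ..." else ""
      ))
    }
    g
  })
  landuse_series(grids)
}

#' Coarsen a fraction grid by an integer factor
#'
#' Aggregates `factor x factor` blocks to their land-area-weighted mean
#' fraction. Nodata cells are excluded; a block with no data cells is nodata.
#' Partial blocks at the south/east edges are allowed and weighted by the area
#' actually present. On a planar grid the aggregation conserves total
#' converted area exactly; on geographic grids the coarse cell-area
#' approximation introduces an error of order the latitude span of a block.
#'
#' @param grid a [fraction_grid()].
#' @param factor positive integer aggregation factor.
#' @return a coarser [fraction_grid()].
#' @export
coarsen <- function(grid, factor) {
  factor <- as.integer(factor)
  if (is.na(factor) || factor < 1L) rlang::abort("factor must be a positive integer")
  if (factor == 1L) return(grid)
  v <- grid$values
  a <- cell_area_km2(grid)
  nr <- nrow(v); nc <- ncol(v)
  bi <- (seq_len(nr) - 1L) %/% factor + 1L
  bj <- (seq_len(nc) - 1L) %/% factor + 1L
  nbr <- max(bi); nbc <- max(bj)
  grp <- matrix(bi, nr, nc) + (matrix(bj, nr, nc, byrow = TRUE) - 1L) * nbr
  ok <- !is.na(v)
  num <- rowsum(as.vector(v * a)[ok], group = as.vector(grp)[ok])
  den <- rowsum(as.vector(a)[ok], group = as.vector(grp)[ok])
  out <- matrix(NA_real_, nbr, nbc)
  out[as.integer(rownames(num))] <- num / den
  fraction_grid(out, grid$year, grid$x0, grid$y1,
                dx = grid$dx * factor, dy = grid$dy * factor, crs = grid$crs)
}
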