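# Register filtering and construction of merged protection layers.

#' Filter a site register for analysis
#'
#' Applies the inclusion rules used for effectiveness analyses: only sites
#' managed primarily for biodiversity (IUCN categories Ia-IV) are kept;
#' point-only records are dropped (they are below the resolution of the land
#' cover grids); polygons smaller than `min_area_km2` (measured from geometry,
#' not from the reported attribute) are dropped. In `"historical"` mode,
#' records with no establishment date are also dropped, as are records
#' gazetted after `latest_gazettement_year` (too little post-gazettement time
#' to estimate a clearance rate). In `"current"` mode missing-date records are
#' retained: their presence in the register confirms establishment even when
#' the date is unknown.
#'
#' Rules are applied in a fixed order (category, unknown category, point-only,
#' sub-minimum area, missing date, gazetted too late) so each dropped record
#' is counted under exactly one rule.
#'
#' @param reg a register tibble (see [pa_register()]).
#' @param mode `"current"` or `"historical"`.
#' @param min_area_km2 minimum geometric area retained (default 1).
#' @param latest_gazettement_year in historical mode, drop records established
#'   after this year (`NULL` to keep all dated records).
#' @param crs CRS of the register geometry.
#' @return the retained register rows, with a `filter_report` tibble attached
#'   as attribute `"filter_report"` (see [filter_report()]).
#' @examples
#' reg <- pa_register(c("a", "b"), c(0, 5), c(2, 9), c(0, 5), c(2, 9),
#'                    c("II", "V"), c(1920, 1950))
#' kept <- filter_register(reg, "historical")
#' filter_report(kept)
#' @export
filter_register <- function(reg, mode = c("current", "historical"),
                            min_area_km2 = 1,
                            latest_gazettement_year = NULL,
                            crs = "planar_km") {
  mode <- rlang::arg_match(mode)
  if (nrow(reg) == 0) rlang::abort("register is empty")
  if (min_area_km2 < 0) rlang::abort("min_area_km2 must be >= 0")
  validate_register(reg)

  keep <- rep(TRUE, nrow(reg))
  drops <- list()
  take <- function(cond) {
    hit <- keep & cond
    keep[hit] <<- FALSE
    sum(hit)
  }

  known <- reg$iucn_category %in% setdiff(iucn_categories(), "unknown")
  strict <- reg$iucn_category %in% c("Ia", "Ib", "II", "III", "IV")
  drops$category_v_vi <- take(known & !strict)
  drops$category_unknown <- take(!known)
  drops$point_only <- take(reg$geom_type == "point")
  area <- site_area_km2(reg, crs)
  drops$below_min_area <- take(reg$geom_type == "polygon" & area < min_area_km2)
  if (mode == "historical") {
    drops$missing_date <- take(is.na(reg$establishment_year))
    if (!is.null(latest_gazettement_year)) {
      drops$gazetted_too_late <- take(!is.na(reg$establishment_year) &
                                        reg$establishment_year > latest_gazettement_year)
    }
  }

  if (!any(keep)) {
    rlang::abort(paste0("no sites retained after filtering (", nrow(reg),
                        " records all excluded)"))
  }
  report <- tibble::tibble(
    rule = names(drops),
    n_dropped = unlist(drops, use.names = FALSE)
  )
  attr(report, "n_input") <- nrow(reg)
  attr(report, "n_retained") <- sum(keep)
  out <- reg[keep, , drop = FALSE]
  attr(out, "filter_report") <- report
  out
}

#' Retrieve the filter report attached to a filtered register
#'
#' @param filtered the tibble returned by [filter_register()].
#' @return tibble with columns `rule`, `n_dropped`, plus attributes
#'   `n_input` and `n_retained` (`n_input = n_retained + sum(n_dropped)`).
#' @export
filter_report <- function(filtered) {
  rep <- attr(filtered, "filter_report", exact = TRUE)
  if (is.null(rep)) rlang::abort("no filter_report attribute; was this produced by filter_register()?")
  rep
}

#' Merge sites into a single non-overlapping protection layer
#'
#' Geometric union of the (already filtered) site footprints: overlapping
#' areas are counted once, and every part of the union is tagged with the
#' strictest IUCN category among the sites covering it. If `reference_year`
#' is given, only sites established by that year enter the layer (records
#' with no date are excluded, since their establishment time is unknown).
#'
#' @param reg filtered register tibble (polygon records only).
#' @param reference_year integer year the layer refers to, or `NULL` for all
#'   records.
#' @param crs CRS of the register geometry.
#' @return a `protection_layer`: list with `reference_year`, `parts` (tibble
#'   of disjoint rectangles with `strictest_category`), `total_area_km2`,
#'   `crs`.
#' @export
merge_layer <- function(reg, reference_year = NULL, crs = "planar_km") {
  validate_register(reg)
  if (any(reg$geom_type != "polygon")) {
    bad <- reg$site_id[reg$geom_type != "polygon"]
    rlang::abort(paste0("cannot merge non-polygon record(s): ",
                        paste(utils::head(bad, 5), collapse = ", "),
                        " (filter the register first)"))
  }
  use <- reg
  if (!is.null(reference_year)) {
    use <- dplyr::filter(reg, !is.na(.data$establishment_year),
                         .data$establishment_year <= reference_year)
  }
  parts <- decompose_rects(
    use[, c("xmin", "xmax", "ymin", "ymax")],
    cat_rank = category_rank(use$iucn_category)
  )
  parts$strictest_category <- iucn_categories()[parts$cat_rank]
  parts$cat_rank <- NULL
  total <- sum(rect_area_km2(parts$xmin, parts$xmax, parts$ymin, parts$ymax, crs))
  structure(
    list(reference_year = if (is.null(reference_year)) NA_integer_ else as.integer(reference_year),
         parts = parts, total_area_km2 = total, crs = crs),
    class = "protection_layer"
  )
}

#' @export
print.protection_layer <- function(x, ...) {
  cat(sprintf("<protection_layer> year %s: %d disjoint parts, %.2f km^2 (%s)\n",
              ifelse(is.na(x$reference_year), "(all)", x$reference_year),
              nrow(x$parts), x$total_area_km2, x$crs))
  invisible(x)
}

#' Decadal historical protection layers
#'
#' One merged layer per decade, each containing exactly the sites established
#' by that decade year. A site established in a non-decadal year enters the
#' first decade year greater than or equal to it (1972 enters the 1980 layer):
#' rounding up avoids crediting protection before it existed.
#'
#' @param reg register filtered in historical mode.
#' @param decades strictly increasing integer decade years (e.g.
#'   `seq(1880, 2000, 10)`).
#' @param crs CRS of the register geometry.
#' @return list of `protection_layer` objects, one per decade.
#' @export
historical_layers <- function(reg, decades, crs = "planar_km") {
  if (any(diff(decades) <= 0)) rlang::abort("decades must be strictly increasing")
  purrr::map(decades, function(d) merge_layer(reg, reference_year = d, crs = crs))
}

#' First decade year at or after an establishment year
#'
#' The rounding-up convention shared by layer construction and the pre/post
#' gazettement split: a site established in 1972 is first credited with
#' protection in the 1980 layer, and the 1970-1980 conversion increment is
#' counted as pre-gazettement.
#'
#' @param establishment_year integer vector (may contain `NA`).
#' @param decades strictly increasing decade years.
#' @return integer vector of decade years (`NA` where the establishment year
#'   is missing or after the last decade).
#' @export
establishment_decade <- function(establishment_year, decades) {
  vapply(establishment_year, function(y) {
    if (is.na(y)) return(NA_integer_)
    d <- decades[decades >= y]
    if (!length(d)) NA_integer_ else as.integer(d[1])
  }, integer(1))
}
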