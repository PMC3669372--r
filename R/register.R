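# The site register: one row per protected area.
#
# A register is a plain tibble so it can be built, filtered and joined with
# ordinary dplyr verbs. Geometry is restricted to axis-aligned rectangles
# (xmin/xmax/ymin/ymax) and point records (xmin == xmax, ymin == ymax with
# geom_type "point").

#' IUCN management categories ordered by strictness
#'
#' Strictness order Ia < Ib < II < III < IV < V < VI (lower rank = more
#' strictly managed), with `"unknown"` last. Overlap resolution in
#' [merge_layer()] assigns the lowest-rank category.
#'
#' @return character vector of category codes, strictest first.
#' @export
iucn_categories <- function() c("Ia", "Ib", "II", "III", "IV", "V", "VI", "unknown")

category_rank <- function(cat) {
  r <- match(cat, iucn_categories())
  r[is.na(r)] <- match("unknown", iucn_categories())
  as.integer(r)
}

register_cols <- c("site_id", "geom_type", "xmin", "xmax", "ymin", "ymax",
                   "iucn_category", "establishment_year", "reported_area_km2")

#' Assemble a site register tibble
#'
#' Light constructor/validator for the register layout used throughout the
#' package. Most users will instead get a register from [simulate_register()]
#' or [read_register_geojson()].
#'
#' @param site_id character identifiers (unique).
#' @param xmin,xmax,ymin,ymax rectangle bounds; for point records give the
#'   point coordinate in both min and max.
#' @param iucn_category category codes from [iucn_categories()].
#' @param establishment_year integer year of gazettement (`NA` if unknown).
#' @param geom_type `"polygon"` or `"point"`.
#' @param reported_area_km2 area as reported in the register attributes
#'   (informational; filters measure area from geometry).
#' @return a register tibble.
#' @export
pa_register <- function(site_id, xmin, xmax, ymin, ymax, iucn_category,
                        establishment_year = NA_integer_,
                        geom_type = "polygon",
                        reported_area_km2 = NA_real_) {
  reg <- tibble::tibble(
    site_id = as.character(site_id),
    geom_type = geom_type,
    xmin = as.numeric(xmin), xmax = as.numeric(xmax),
    ymin = as.numeric(ymin), ymax = as.numeric(ymax),
    iucn_category = as.character(iucn_category),
    establishment_year = as.integer(establishment_year),
    reported_area_km2 = as.numeric(reported_area_km2)
  )
  validate_register(reg)
  reg
}

validate_register <- function(reg) {
  missing_cols <- setdiff(register_cols, names(reg))
  if (length(missing_cols)) {
    rlang::abort(paste0("register is missing columns: ",
                        paste(missing_cols, collapse = ", ")))
  }
  if (anyDuplicated(reg$site_id)) rlang::abort("site_id values must be unique")
  if (!all(reg$geom_type %in% c("polygon", "point"))) {
    rlang::abort("geom_type must be 'polygon' or 'point'")
  }
  poly <- reg$geom_type == "polygon"
  bad <- poly & (is.na(reg$xmin) | is.na(reg$xmax) | is.na(reg$ymin) | is.na(reg$ymax) |
                   reg$xmax <= reg$xmin | reg$ymax <= reg$ymin)
  if (any(bad)) {
    rlang::abort(paste0("invalid (degenerate) polygon geometry for site(s): ",
                        paste(utils::head(reg$site_id[bad], 5), collapse = ", ")))
  }
  invisible(reg)
}

#' Geometric area of each register record, in km^2
#'
#' Polygon records are measured from geometry; point records have no
#' footprint and return `NA`.
#'
#' @param reg a register tibble.
#' @param crs `"planar_km"` or `"geographic"`.
#' @return numeric vector of areas.
#' @export
site_area_km2 <- function(reg, crs = "planar_km") {
  a <- rect_area_km2(reg$xmin, reg$xmax, reg$ymin, reg$ymax, crs)
  a[reg$geom_type != "polygon"] <- NA_real_
  a
}
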