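# File interchange: GeoJSON registers and layers, attribute CSVs, JSON
# manifests. Geometry on disk is restricted to axis-aligned rectangles and
# points, matching the package's geometry model.

rect_ring <- function(xmin, xmax, ymin, ymax) {
  list(list(
    c(xmin, ymin), c(xmax, ymin), c(xmax, ymax), c(xmin, ymax), c(xmin, ymin)
  ))
}

#' Write a site register as GeoJSON (plus optional attribute CSV)
#'
#' @param reg register tibble.
#' @param path output GeoJSON path.
#' @param csv_path optional path for an attribute CSV with columns
#'   `site_id`, `iucn_category`, `establishment_year`, `reported_area_km2`.
#' @return `path`, invisibly.
#' @export
write_register_geojson <- function(reg, path, csv_path = NULL) {
  validate_register(reg)
  feats <- purrr::map(seq_len(nrow(reg)), function(i) {
    geom <- if (reg$geom_type[i] == "point") {
      list(type = "Point", coordinates = c(reg$xmin[i], reg$ymin[i]))
    } else {
      list(type = "Polygon",
           coordinates = rect_ring(reg$xmin[i], reg$xmax[i],
                                   reg$ymin[i], reg$ymax[i]))
    }
    list(
      type = "Feature", geometry = geom,
      properties = list(
        site_id = reg$site_id[i],
        iucn_cat = reg$iucn_category[i],
        status_yr = reg$establishment_year[i],
        rep_area = reg$reported_area_km2[i]
      )
    )
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA, na = "null",
                       pretty = TRUE)
  if (!is.null(csv_path)) {
    utils::write.csv(
      reg[, c("site_id", "iucn_category", "establishment_year",
              "reported_area_km2")],
      csv_path, row.names = FALSE
    )
  }
  invisible(path)
}

#' Read a site register from GeoJSON
#'
#' Accepts Point features and Polygon features whose single ring is an
#' axis-aligned rectangle; any other geometry raises an error (this package
#' has no general polygon engine). Attribute names are configurable; defaults
#' match common register conventions.
#'
#' @param path GeoJSON file.
#' @param fields named list mapping register fields to property names
#'   (defaults: `iucn_cat`, `status_yr`, `rep_area`, `site_id`).
#' @return a register tibble.
#' @export
read_register_geojson <- function(path,
                                  fields = list(site_id = "site_id",
                                                iucn_category = "iucn_cat",
                                                establishment_year = "status_yr",
                                                reported_area_km2 = "rep_area")) {
  gj <- jsonlite::read_json(path)
  if (!identical(gj$type, "FeatureCollection")) {
    rlang::abort("expected a GeoJSON FeatureCollection")
  }
  prop_chr <- function(props, key, default = NA) {
    v <- props[[key]]
    if (is.null(v)) default else v
  }
  rows <- purrr::imap(gj$features, function(ft, i) {
    g <- ft$geometry
    props <- ft$properties
    sid <- as.character(prop_chr(props, fields$site_id, paste0("feature_", i)))
    if (identical(g$type, "Point")) {
      xy <- unlist(g$coordinates)
      bounds <- c(xy[1], xy[1], xy[2], xy[2])
      gt <- "point"
    } else if (identical(g$type, "Polygon")) {
      ring <- g$coordinates[[1]]
      xs <- vapply(ring, function(p) as.numeric(p[[1]]), numeric(1))
      ys <- vapply(ring, function(p) as.numeric(p[[2]]), numeric(1))
      # shoelace area must equal the bounding-box area for a rectangle
      shoelace <- abs(sum(xs * c(ys[-1], ys[1]) - c(xs[-1], xs[1]) * ys)) / 2
      bb <- (max(xs) - min(xs)) * (max(ys) - min(ys))
      if (!isTRUE(all.equal(shoelace, bb, tolerance = 1e-9))) {
        rlang::abort(paste0(
          "site ", sid, ": only axis-aligned rectangular polygons are supported"
        ))
      }
      bounds <- c(min(xs), max(xs), min(ys), max(ys))
      gt <- "polygon"
    } else {
      rlang::abort(paste0("site ", sid, ": unsupported geometry type ", g$type))
    }
    tibble::tibble(
      site_id = sid, geom_type = gt,
      xmin = bounds[1], xmax = bounds[2], ymin = bounds[3], ymax = bounds[4],
      iucn_category = as.character(prop_chr(props, fields$iucn_category, "unknown")),
      establishment_year = {
        v <- prop_chr(props, fields$establishment_year, NA)
        if (is.null(v) || is.na(suppressWarnings(as.integer(v)))) NA_integer_ else as.integer(v)
      },
      reported_area_km2 = {
        v <- prop_chr(props, fields$reported_area_km2, NA)
        if (is.null(v)) NA_real_ else suppressWarnings(as.numeric(v))
      }
    )
  })
  reg <- dplyr::bind_rows(rows)
  validate_register(reg)
  reg
}

#' Write a merged protection layer as GeoJSON
#'
#' One Polygon feature per disjoint part, with its `strictest_category`
#' property.
#'
#' @param layer a [merge_layer()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_layer_geojson <- function(layer, path) {
  feats <- purrr::map(seq_len(nrow(layer$parts)), function(i) {
    p <- layer$parts[i, ]
    list(
      type = "Feature",
      geometry = list(type = "Polygon",
                      coordinates = rect_ring(p$xmin, p$xmax, p$ymin, p$ymax)),
      properties = list(strictest_category = p$strictest_category)
    )
  })
  jsonlite::write_json(
    list(type = "FeatureCollection",
         reference_year = layer$reference_year,
         total_area_km2 = layer$total_area_km2,
         features = feats),
    path, auto_unbox = TRUE, digits = NA, na = "null"
  )
  invisible(path)
}

#' Write a zonal trajectory as a long-format CSV
#'
#' Columns `year`, `zone` (`inside`/`outside`), `pct_converted`, `area_km2`.
#'
#' @param traj tibble from [trajectory()] or [zonal_summary()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_zonal_csv <- function(traj, path) {
  long <- tidyr::pivot_longer(
    traj[, c("year", "pct_converted_inside", "pct_converted_outside",
             "area_inside_km2", "area_outside_km2")],
    -"year",
    names_to = c(".value", "zone"),
    names_pattern = "(pct_converted|area)_(inside|outside)(?:_km2)?"
  )
  names(long)[names(long) == "area"] <- "area_km2"
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}
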