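# Pipeline orchestration: configuration, the full analysis run, and the
# synthetic demonstration.

#' Pipeline configuration
#'
#' Bundles the inputs and tuning parameters of a full effectiveness analysis.
#' Defaults encode the standard analysis choices: a 1 km^2 minimum site size,
#' sensitivity reruns at 5/10/25 km^2, historical layers for each decade from
#' 1880, a 1994 gazettement cutoff (sites established later have too little
#' post-gazettement time), 95% confidence, and exact fractional cell
#' coverage.
#'
#' @param register a register tibble (see [pa_register()]).
#' @param series a [landuse_series()] of fraction grids.
#' @param region_mask optional logical matrix of analysis-region cells.
#' @param min_area_km2 minimum site area retained (km^2).
#' @param sensitivity_thresholds additional minimum-size thresholds for the
#'   sensitivity rerun of the current-status summaries.
#' @param decades decade years for the historical layers (default: series
#'   years from the fourth decade on, i.e. 1880-2000 for an 1850 series).
#' @param latest_gazettement_year cutoff for the historical analysis.
#' @param confidence confidence level for SMA intervals.
#' @param coverage_mode `"fractional"` or `"cell_centre"`.
#' @param crs CRS shared by register and grids.
#' @param seed seed recorded in (and used by any resampling in) the run.
#' @param output_dir optional directory; when set, [run_pipeline()] writes
#'   CSV/GeoJSON/JSON outputs there.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(register, series, region_mask = NULL,
                            min_area_km2 = 1,
                            sensitivity_thresholds = c(5, 10, 25),
                            decades = NULL,
                            latest_gazettement_year = 1994,
                            confidence = 0.95,
                            coverage_mode = c("fractional", "cell_centre"),
                            crs = "planar_km",
                            seed = 1L,
                            output_dir = NULL) {
  coverage_mode <- rlang::arg_match(coverage_mode)
  years <- series_years(series)
  if (is.null(decades)) decades <- years[years >= min(years) + 30]
  if (!all(decades %in% years)) {
    rlang::abort("decades must be a subset of the series years")
  }
  structure(
    list(register = register, series = series, region_mask = region_mask,
         min_area_km2 = min_area_km2,
         sensitivity_thresholds = sensitivity_thresholds,
         decades = as.integer(decades),
         latest_gazettement_year = latest_gazettement_year,
         confidence = confidence, coverage_mode = coverage_mode,
         crs = crs, seed = as.integer(seed), output_dir = output_dir),
    class = "pipeline_config"
  )
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    rlang::abort(paste0("pipeline stage '", name, "' failed: ",
                        conditionMessage(e)), parent = e)
  })
}

#' Run the full effectiveness analysis
#'
#' Executes filter, merge, historical layers, overlay and statistics, and
#' returns a results manifest. Stages: (1) current-mode filtering and the
#' current merged layer; (2) the current-year inside/outside summary, per-site
#' summaries, conversion histogram, size-quantile profile, size-conversion
#' scaling, and minimum-size sensitivity reruns; (3) historical-mode
#' filtering, decadal layers, the inside/outside trajectory and its two SMA
#' fits (x = decades since the series start, y = percent converted) with the
#' common-slope test; (4) per-site trajectories, pre/post gazettement rates
#' and the paired t-test. If `config$output_dir` is set, tables are also
#' written as CSV/GeoJSON/JSON.
#'
#' @param config a [pipeline_config()].
#' @return a `pipeline_manifest` list; see the vignette for a tour.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  series <- config$series
  years <- series_years(series)
  final_grid <- series[[length(series)]]
  mode <- config$coverage_mode

  # --- stage: filter (current) ---
  current <- stage("filter_current", filter_register(
    config$register, mode = "current", min_area_km2 = config$min_area_km2,
    crs = config$crs
  ))
  current_report <- filter_report(current)

  # --- stage: current layer + zonal summary ---
  current_layer <- stage("merge_current", merge_layer(current, crs = config$crs))
  cov <- stage("coverage", coverage(current_layer, final_grid, mode = mode))
  current_zonal <- stage("zonal_current",
                         zonal_summary(final_grid, cov, config$region_mask))

  # --- stage: per-site current statistics ---
  site_now <- stage("per_site", per_site_summary(
    current, final_grid, region_mask = config$region_mask, mode = mode
  ))
  site_ok <- site_now[site_now$defined, , drop = FALSE]
  hist_counts <- stage("histogram", conversion_histogram(site_ok$pct_converted))
  profile <- stage("quantile_profile", {
    if (nrow(site_ok) >= 11) quantile_profile(site_ok, k = 11) else NULL
  })
  scaling <- stage("size_scaling", size_scaling(site_ok, config$confidence))

  sensitivity <- stage("sensitivity", purrr::map_dfr(
    config$sensitivity_thresholds, function(thr) {
      keep <- filter_register(config$register, mode = "current",
                              min_area_km2 = thr, crs = config$crs)
      lay <- merge_layer(keep, crs = config$crs)
      zs <- zonal_summary(final_grid, coverage(lay, final_grid, mode = mode),
                          config$region_mask)
      ps <- per_site_summary(keep, final_grid, region_mask = config$region_mask,
                             mode = mode)
      tibble::tibble(
        min_area_km2 = thr,
        n_sites = nrow(keep),
        mean_site_pct = mean(ps$pct_converted[ps$defined]),
        pct_converted_inside = zs$pct_converted_inside
      )
    }
  ))

  # --- stage: historical trajectory ---
  historical <- stage("filter_historical", filter_register(
    config$register, mode = "historical", min_area_km2 = config$min_area_km2,
    latest_gazettement_year = config$latest_gazettement_year, crs = config$crs
  ))
  historical_report <- filter_report(historical)
  layers <- stage("historical_layers",
                  historical_layers(historical, config$decades, crs = config$crs))
  traj <- stage("trajectory",
                trajectory(layers, series, config$region_mask, mode = mode))

  traj_def <- traj[traj$inside_defined & traj$outside_defined, , drop = FALSE]
  x_dec <- (traj_def$year - min(years)) / 10
  sma_inside <- stage("sma_inside", sma_fit(
    x_dec, traj_def$pct_converted_inside, confidence = config$confidence,
    xlab = "decades since series start", ylab = "% converted inside"
  ))
  sma_outside <- stage("sma_outside", sma_fit(
    x_dec, traj_def$pct_converted_outside, confidence = config$confidence,
    xlab = "decades since series start", ylab = "% converted outside"
  ))
  slope_test <- stage("slope_test", sma_slope_test(
    x_dec, traj_def$pct_converted_outside, x_dec, traj_def$pct_converted_inside
  ))

  # --- stage: pre/post gazettement ---
  site_traj <- stage("site_trajectories", per_site_trajectory(
    historical, series, region_mask = config$region_mask, mode = mode
  ))
  rates <- stage("gazettement_rates", gazettement_rates(site_traj, historical))
  rates_in <- rates[rates$included, , drop = FALSE]
  prepost <- stage("paired_t", paired_t(rates_in$pre_rate, rates_in$post_rate))

  manifest <- structure(list(
    seed = config$seed,
    coverage_mode = mode,
    filter_reports = list(current = current_report, historical = historical_report),
    estate_area_km2 = current_layer$total_area_km2,
    current = list(
      zonal = current_zonal,
      per_site = site_now,
      mean_site_pct = mean(site_ok$pct_converted),
      histogram = hist_counts,
      n_above_half = attr(hist_counts, "n_above_half"),
      quantile_profile = profile,
      size_scaling = scaling,
      sensitivity = sensitivity
    ),
    historical = list(
      trajectory = traj,
      sma_inside = sma_inside,
      sma_outside = sma_outside,
      slope_test = slope_test,
      gazettement_rates = rates,
      mean_pre_rate = mean(rates_in$pre_rate),
      mean_post_rate = mean(rates_in$post_rate),
      paired_t = prepost,
      n_sites_paired = nrow(rates_in)
    )
  ), class = "pipeline_manifest")

  if (!is.null(config$output_dir)) {
    write_manifest(manifest, config, config$output_dir)
  }
  manifest
}

write_manifest <- function(manifest, config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(manifest$historical$trajectory,
                   file.path(dir, "trajectory.csv"), row.names = FALSE)
  write_zonal_csv(manifest$historical$trajectory,
                  file.path(dir, "trajectory_long.csv"))
  utils::write.csv(manifest$current$per_site,
                   file.path(dir, "per_site.csv"), row.names = FALSE)
  utils::write.csv(manifest$current$histogram,
                   file.path(dir, "histogram.csv"), row.names = FALSE)
  if (!is.null(manifest$current$quantile_profile)) {
    utils::write.csv(manifest$current$quantile_profile,
                     file.path(dir, "quantile_profile.csv"), row.names = FALSE)
  }
  jsonlite::write_json(manifest_summary(manifest),
                       file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       pretty = TRUE)
  invisible(dir)
}

#' Flat numeric summary of a pipeline manifest
#'
#' The headline statistics of a run as a named list of scalars, suitable for
#' JSON serialisation or quick inspection.
#'
#' @param manifest a [run_pipeline()] result.
#' @return named list.
#' @export
manifest_summary <- function(manifest) {
  cz <- manifest$current$zonal
  h <- manifest$historical
  list(
    seed = manifest$seed,
    estate_area_km2 = manifest$estate_area_km2,
    pct_converted_inside = cz$pct_converted_inside,
    pct_converted_outside = cz$pct_converted_outside,
    mean_site_pct_converted = manifest$current$mean_site_pct,
    n_sites_above_half_converted = manifest$current$n_above_half,
    size_scaling_slope = manifest$current$size_scaling$slope,
    size_scaling_ci_low = manifest$current$size_scaling$ci_low,
    size_scaling_ci_high = manifest$current$size_scaling$ci_high,
    sma_slope_inside = h$sma_inside$slope,
    sma_slope_outside = h$sma_outside$slope,
    slope_test_p = h$slope_test$p_value,
    mean_pre_rate = h$mean_pre_rate,
    mean_post_rate = h$mean_post_rate,
    paired_t = h$paired_t$statistic,
    paired_t_df = h$paired_t$df,
    paired_t_p = h$paired_t$p_value,
    n_sites_paired = h$n_sites_paired
  )
}

#' @export
print.pipeline_manifest <- function(x, ...) {
  s <- manifest_summary(x)
  cat("<pipeline_manifest>\n")
  cat(sprintf("  estate area: %.0f km^2\n", s$estate_area_km2))
  cat(sprintf("  converted inside %.2f%% vs outside %.2f%% (final year)\n",
              s$pct_converted_inside, s$pct_converted_outside))
  cat(sprintf("  mean per-site conversion %.1f%%; %d sites > 50%% converted\n",
              s$mean_site_pct_converted, s$n_sites_above_half_converted))
  cat(sprintf("  trajectory SMA slopes: inside %.4f, outside %.4f (p = %.3f)\n",
              s$sma_slope_inside, s$sma_slope_outside, s$slope_test_p))
  cat(sprintf("  conversion rate %.3f%%/decade before vs %.3f%%/decade after gazettement\n",
              s$mean_pre_rate, s$mean_post_rate))
  cat(sprintf("  paired t = %.3f, df = %d, p = %.3f (%d sites)\n",
              s$paired_t, s$paired_t_df, s$paired_t_p, s$n_sites_paired))
  invisible(x)
}

#' Simulate a landscape and run the full pipeline on it
#'
#' End-to-end demonstration: simulates a register and landscape under a given
#' protection effect, runs [run_pipeline()], and prints the headline
#' comparisons.
#'
#' @param seed integer seed.
#' @param protection_multiplier true hazard multiplier inside sites (0.5 by
#'   default; 1 is the no-effect null).
#' @param n_sites number of simulated sites.
#' @param quiet suppress printing.
#' @param ... further arguments to [sim_config()].
#' @return the pipeline manifest, invisibly; its `ground_truth` element holds
#'   the simulator's truth.
#' @export
run_demo <- function(seed = 1L, protection_multiplier = 0.5, n_sites = 100,
                     quiet = FALSE, ...) {
  config <- sim_config(seed = seed,
                       protection_multiplier = protection_multiplier,
                       n_sites = n_sites, ...)
  reg <- simulate_register(config)
  sim <- simulate_landscape(config, reg)
  pc <- pipeline_config(reg, sim$series, seed = seed)
  manifest <- run_pipeline(pc)
  manifest$ground_truth <- sim$ground_truth
  if (!quiet) print(manifest)
  invisible(manifest)
}
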