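# Coverage fields and zonal statistics against analytic cases and the
# per-cell brute-force oracle.

test_that("coverage is exact for whole, half and no cells", {
  g <- fraction_grid(matrix(0.5, 4, 4), 2000, dx = 2)
  # one full grid cell: cell (row 2, col 3) spans x [4,6], y [4,6]
  one <- merge_layer(pa_register("a", 4, 6, 4, 6, "II", 1900L))
  cov <- coverage(one, g)
  expect_equal(cov[2, 3], 1)
  expect_equal(sum(cov), 1)

  # square covering exactly half of one cell
  half <- merge_layer(pa_register("b", 4, 5, 4, 6, "II", 1900L))
  ch <- coverage(half, g)
  expect_equal(ch[2, 3], 0.5)
  expect_equal(sum(ch), 0.5)

  # empty layer
  none <- merge_layer(pa_register("c", 0, 1, 0, 1, "II", 1980L),
                      reference_year = 1900)
  c0 <- coverage(none, g)
  expect_true(all(c0 == 0))
  expect_equal(sum(c0 * cell_area_km2(g)), 0)
})

test_that("coverage integrates to the layer area and partitions the region", {
  set.seed(12)
  g <- random_grid(20, 25, dx = 1.5)
  reg <- random_sites(8, g)
  lay <- merge_layer(reg)
  cov <- coverage(lay, g)
  expect_true(all(cov >= 0 & cov <= 1))
  expect_equal(sum(cov * cell_area_km2(g)), lay$total_area_km2,
               tolerance = 1e-9)
  # coverage + complement reconstructs the region exactly
  expect_equal(sum((cov + (1 - cov)) * cell_area_km2(g)),
               sum(cell_area_km2(g)), tolerance = 1e-12)
})

test_that("CRS mismatch between layer and grid errors", {
  g <- fraction_grid(matrix(0.5, 4, 4), 2000, dx = 0.1, crs = "geographic")
  lay <- merge_layer(pa_register("a", 0, 0.2, 0, 0.2, "II", 1900L))
  expect_error(coverage(lay, g), "CRS mismatch")
})

test_that("zonal percentages behave on uniform and degenerate landscapes", {
  g <- fraction_grid(matrix(0.4, 6, 6), 2000, dx = 1)
  lay <- merge_layer(pa_register("a", 1, 3.5, 1, 4, "II", 1900L))
  zs <- zonal_summary(g, coverage(lay, g))
  expect_equal(zs$pct_converted_inside, 40)
  expect_equal(zs$pct_converted_outside, 40)

  # layer covering the whole region: outside undefined and flagged, not 0
  all_lay <- merge_layer(pa_register("a", 0, 6, 0, 6, "II", 1900L))
  zs2 <- zonal_summary(g, coverage(all_lay, g))
  expect_false(zs2$outside_defined)
  expect_true(is.na(zs2$pct_converted_outside))
  expect_equal(zs2$pct_converted_inside, 40)

  # empty layer: inside undefined and flagged
  none <- merge_layer(pa_register("a", 0, 1, 0, 1, "II", 1980L),
                      reference_year = 1900)
  zs3 <- zonal_summary(g, coverage(none, g))
  expect_false(zs3$inside_defined)
  expect_true(is.na(zs3$pct_converted_inside))
})

test_that("a 3x3 grid with a one-cell layer matches per-cell enumeration", {
  vals <- matrix(c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6, 0.7, 0.8, 0.9), 3, 3)
  g <- fraction_grid(vals, 2000, dx = 1)
  reg <- pa_register("a", 1, 2, 1, 2, "II", 1900L) # centre cell
  zs <- zonal_summary(g, coverage(merge_layer(reg), g))
  oz <- oracle_zonal(g, reg)
  expect_equal(zs$pct_converted_inside, oz$pct_inside, tolerance = 1e-12)
  expect_equal(zs$pct_converted_outside, oz$pct_outside, tolerance = 1e-12)
  expect_equal(zs$pct_converted_inside, 100 * vals[2, 2])
})

test_that("per-site summaries match analytic values and the brute-force oracle", {
  # site covering two cells of fraction 0.2 and 0.6 with equal areas
  g <- fraction_grid(matrix(c(0.2, 0.6), 1, 2), 2000, dx = 1)
  reg <- pa_register("a", 0, 2, 0, 1, "II", 1900L)
  ps <- per_site_summary(reg, g)
  expect_equal(ps$pct_converted, 40)

  # site wholly inside one cell
  g2 <- fraction_grid(matrix(0.2786, 2, 2), 2000, dx = 10)
  reg2 <- pa_register("b", 2, 5, 2, 6, "II", 1900L)
  expect_equal(per_site_summary(reg2, g2)$pct_converted, 27.86)

  # 5 random rectangles on a random grid vs the oracle
  set.seed(77)
  g3 <- random_grid(15, 15, dx = 2)
  reg3 <- random_sites(5, g3)
  ps3 <- per_site_summary(reg3, g3)
  for (s in seq_len(5)) {
    expect_equal(ps3$pct_converted[s],
                 oracle_site_pct(reg3[s, ], g3), tolerance = 1e-9)
  }

  # a site with no land under it is flagged, not zeroed
  gna <- fraction_grid(matrix(NA_real_, 3, 3), 2000, dx = 1)
  psna <- per_site_summary(pa_register("c", 0, 1, 0, 1, "II", 1900L), gna)
  expect_false(psna$defined)
  expect_true(is.na(psna$pct_converted))
})

test_that("cell-centre coverage mode marks whole cells by centre membership", {
  g <- fraction_grid(matrix(0.5, 4, 4), 2000, dx = 2)
  # small square around the centre of cell (2, 3)
  lay <- merge_layer(pa_register("a", 4.6, 5.4, 4.6, 5.4, "II", 1900L))
  covf <- coverage(lay, g)
  covc <- coverage(lay, g, mode = "cell_centre")
  expect_lt(covf[2, 3], 1)
  expect_equal(covc[2, 3], 1)
  expect_equal(sum(covc), 1)
})

test_that("converted area is conserved between zones every year", {
  set.seed(41)
  cfg <- sim_config(grid_rows = 20, grid_cols = 20, n_sites = 8,
                    base_hazard = 0.04, seed = 13)
  reg <- simulate_register(cfg)
  sim <- simulate_landscape(cfg, reg)
  hist <- filter_register(reg, "historical", latest_gazettement_year = 1994)
  layers <- historical_layers(hist, seq(1880L, 2000L, 10L))
  traj <- trajectory(layers, sim$series)
  for (k in seq_len(nrow(traj))) {
    y <- traj$year[k]
    g <- sim$series[[match(y, series_years(sim$series))]]
    total_converted <- sum(g$values * cell_area_km2(g))
    lhs <- sum(traj$pct_converted_inside[k] * traj$area_inside_km2[k] / 100,
               na.rm = TRUE) +
      traj$pct_converted_outside[k] * traj$area_outside_km2[k] / 100
    expect_equal(lhs, total_converted, tolerance = 1e-6)
  }
})

test_that("trajectory joins on year, flags the pre-estate era, and errors without overlap", {
  g1 <- fraction_grid(matrix(0.2, 4, 4), 1900, dx = 1)
  g2 <- fraction_grid(matrix(0.4, 4, 4), 1910, dx = 1)
  series <- landuse_series(list(g1, g2))
  reg <- pa_register("a", 1, 3, 1, 3, "II", 1905L)
  layers <- historical_layers(reg, c(1900L, 1910L))
  traj <- trajectory(layers, series)
  expect_equal(nrow(traj), 2)
  expect_false(traj$inside_defined[1]) # estate empty in 1900
  expect_equal(traj$pct_converted_inside[2], 40)

  late_layers <- historical_layers(reg, c(1950L, 1960L))
  expect_error(trajectory(late_layers, series), "no overlap")
})
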