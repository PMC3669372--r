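# Register filtering and merged protection layers.

make_basic_register <- function() {
  pa_register(
    site_id = paste0("r", 1:10),
    xmin = c(0, 10, 20, 30, 40, 50, 60, 70, 5, 15),
    xmax = c(5, 15, 25, 35, 45, 55, 65, 75, 5, 15.5),
    ymin = rep(0, 10),
    ymax = c(5, 5, 5, 5, 5, 5, 5, 5, 0, 1),
    iucn_category = c("Ia", "Ib", "II", "III", "IV", "II", "IV", "II", "II", "II"),
    establishment_year = c(1900, 1920, 1940, NA, 1960, 1980, 1995, 1970, 1950, 1930),
    geom_type = c(rep("polygon", 8), "point", "polygon")
  )
}

test_that("current-mode filtering drops points and sub-minimum areas only", {
  reg <- make_basic_register()
  reg$geom_type[8] <- "point"
  reg$xmax[8] <- reg$xmin[8]; reg$ymax[8] <- reg$ymin[8]
  # now: 2 points (r8, r9), one 0.5 km^2 sliver (r10), all categories I-IV
  kept <- filter_register(reg, "current", min_area_km2 = 1)
  expect_equal(nrow(kept), 7)
  rep <- filter_report(kept)
  drops <- setNames(rep$n_dropped, rep$rule)
  expect_equal(unname(drops["point_only"]), 2)
  expect_equal(unname(drops["below_min_area"]), 1)
  expect_equal(attr(rep, "n_input"), 10)
  expect_equal(attr(rep, "n_retained") + sum(rep$n_dropped), 10)
  # missing dates are retained in current mode
  expect_true("r4" %in% kept$site_id)
})

test_that("historical-mode filtering also drops missing dates and late sites", {
  reg <- make_basic_register()
  kept <- filter_register(reg, "historical", min_area_km2 = 1,
                          latest_gazettement_year = 1994)
  # r4 missing date, r7 gazetted 1995, r9 point, r10 sub-minimum
  expect_setequal(kept$site_id, c("r1", "r2", "r3", "r5", "r6", "r8"))
  rep <- filter_report(kept)
  expect_equal(attr(rep, "n_retained") + sum(rep$n_dropped), nrow(reg))
})

test_that("category filter keeps only Ia-IV and counts unknown separately", {
  reg <- pa_register(paste0("v", 1:4), c(0, 10, 20, 30), c(5, 15, 25, 35),
                     rep(0, 4), rep(5, 4),
                     c("V", "VI", "weird", "II"), rep(1950L, 4))
  kept <- filter_register(reg, "current")
  expect_equal(kept$site_id, "v4")
  rep <- filter_report(kept)
  drops <- setNames(rep$n_dropped, rep$rule)
  expect_equal(unname(drops["category_v_vi"]), 2)
  expect_equal(unname(drops["category_unknown"]), 1)

  all_v <- pa_register(paste0("w", 1:3), c(0, 10, 20), c(5, 15, 25),
                       rep(0, 3), rep(5, 3), rep("V", 3), rep(1950L, 3))
  expect_error(filter_register(all_v, "current"), "no sites retained")
})

test_that("merging counts overlaps once and keeps the strictest category", {
  # two disjoint 10 km^2 squares
  reg <- pa_register(c("a", "b"), c(0, 10), c(sqrt(10), 10 + sqrt(10)),
                     c(0, 0), c(sqrt(10), sqrt(10)), c("II", "IV"),
                     c(1900L, 1900L))
  expect_equal(merge_layer(reg)$total_area_km2, 20)

  # fully coincident squares, categories II and Ia -> one part, Ia, one area
  co <- pa_register(c("a", "b"), c(0, 0), c(4, 4), c(0, 0), c(4, 4),
                    c("II", "Ia"), c(1900L, 1900L))
  lay <- merge_layer(co)
  expect_equal(lay$total_area_km2, 16)
  expect_equal(unique(lay$parts$strictest_category), "Ia")

  # 10 km^2 squares overlapping by 4 km^2 -> union 16, overlap stricter
  sq <- sqrt(10)
  ov <- pa_register(c("a", "b"),
                    xmin = c(0, sq - 4 / sq), xmax = c(sq, 2 * sq - 4 / sq),
                    ymin = c(0, 0), ymax = c(sq, sq),
                    iucn_category = c("IV", "Ib"),
                    establishment_year = c(1900L, 1900L))
  lay2 <- merge_layer(ov)
  expect_equal(lay2$total_area_km2, 16, tolerance = 1e-12)
  overlap_parts <- lay2$parts[lay2$parts$xmin >= sq - 4 / sq - 1e-12 &
                                lay2$parts$xmax <= sq + 1e-12, ]
  expect_true(all(overlap_parts$strictest_category == "Ib"))
  expect_equal(sum(rect_area <- (overlap_parts$xmax - overlap_parts$xmin) *
                     (overlap_parts$ymax - overlap_parts$ymin)), 4,
               tolerance = 1e-12)
})

test_that("merge is idempotent, order-independent, and bounded by the area sum", {
  set.seed(31)
  g <- fraction_grid(matrix(0.5, 30, 30), 2000, dx = 1)
  reg <- random_sites(12, g)
  lay <- merge_layer(reg)
  # idempotence: merging the merged parts changes nothing
  parts_reg <- pa_register(paste0("p", seq_len(nrow(lay$parts))),
                           lay$parts$xmin, lay$parts$xmax,
                           lay$parts$ymin, lay$parts$ymax,
                           lay$parts$strictest_category, 1900L)
  lay2 <- merge_layer(parts_reg)
  expect_equal(lay2$total_area_km2, lay$total_area_km2, tolerance = 1e-12)
  cov1 <- coverage(lay, g); cov2 <- coverage(lay2, g)
  expect_equal(cov1, cov2, tolerance = 1e-12)

  # order independence
  perm <- reg[sample(nrow(reg)), ]
  lay3 <- merge_layer(perm)
  expect_equal(lay3$total_area_km2, lay$total_area_km2, tolerance = 1e-12)
  expect_equal(coverage(lay3, g), cov1, tolerance = 1e-12)

  # union area <= sum of areas, equality iff disjoint
  expect_lte(lay$total_area_km2, sum(site_area_km2(reg)) + 1e-9)
  disj <- pa_register(c("a", "b"), c(0, 6), c(2, 8), c(0, 0), c(2, 2),
                      c("II", "II"), c(1900L, 1900L))
  expect_equal(merge_layer(disj)$total_area_km2, sum(site_area_km2(disj)))
})

test_that("historical layers respect establishment dates and grow monotonically", {
  reg <- pa_register(c("a", "b"), c(0, 10), c(2, 14), c(0, 0), c(2, 4),
                     c("II", "IV"), c(1889L, 1950L))
  decades <- seq(1880L, 2000L, 10L)
  layers <- historical_layers(reg, decades)
  areas <- vapply(layers, function(l) l$total_area_km2, numeric(1))
  expect_equal(areas[1], 0)              # 1880: nothing yet
  expect_equal(areas[2], 4)              # 1890: the 1889 site only
  expect_equal(areas[8], 20)             # 1950 onward: both
  expect_true(all(diff(areas) >= 0))

  late <- pa_register("z", 0, 2, 0, 2, "II", 2005L)
  empty <- historical_layers(late, decades)
  expect_true(all(vapply(empty, function(l) l$total_area_km2, numeric(1)) == 0))

  expect_error(historical_layers(reg, c(1900L, 1890L)), "increasing")
})

test_that("estate growth ratio is reproduced for a constructed register", {
  # built so the union area is 5 km^2 by 1950 and 320 km^2 by 2000 (64-fold)
  reg <- pa_register(c("early", "late"),
                     xmin = c(0, 100), xmax = c(1, 115.75),
                     ymin = c(0, 0), ymax = c(5, 20),
                     iucn_category = c("II", "II"),
                     establishment_year = c(1945L, 1995L))
  layers <- historical_layers(reg, seq(1950L, 2000L, 10L))
  areas <- vapply(layers, function(l) l$total_area_km2, numeric(1))
  expect_equal(areas[1], 5)
  expect_equal(areas[6] / areas[1], 64)
})

test_that("establishment decade rounds up to the next decadal layer", {
  decades <- seq(1880L, 2000L, 10L)
  expect_equal(establishment_decade(c(1972L, 1880L, 2001L, NA), decades),
               c(1980L, 1880L, NA, NA))
})
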