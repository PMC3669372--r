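# SMA regression, the common-slope test, gazettement rates, paired t,
# size scaling, histogram and quantile profiles.

test_that("SMA recovers a perfect line exactly, with a degenerate CI", {
  x <- 1:10
  fit <- sma_fit(x, 2 * x + 3)
  expect_equal(fit$slope, 2)
  expect_equal(fit$intercept, 3)
  expect_equal(fit$r, 1)
  expect_equal(fit$ci_low, 2, tolerance = 1e-7)
  expect_equal(fit$ci_high, 2, tolerance = 1e-7)
})

test_that("SMA slope equals sign(r) sd(y)/sd(x) and is self-inverse", {
  set.seed(5)
  for (i in 1:20) {
    n <- sample(5:60, 1)
    x <- rnorm(n, sd = runif(1, 0.5, 3))
    y <- runif(1, -2, 2) * x + rnorm(n, sd = runif(1, 0.1, 2))
    fit <- sma_fit(x, y)
    r <- cor(x, y)
    expect_equal(fit$slope, sign(r) * sd(y) / sd(x), tolerance = 1e-14)
    expect_equal(fit$intercept, mean(y) - fit$slope * mean(x), tolerance = 1e-12)
    # symmetry: fitting x on y inverts the slope
    expect_equal(fit$slope * sma_fit(y, x)$slope, 1, tolerance = 1e-12)
    expect_true(fit$ci_low <= fit$slope && fit$slope <= fit$ci_high)
    expect_equal(sign(fit$slope), sign(fit$r))
  }
})

test_that("SMA rejects degenerate inputs", {
  expect_error(sma_fit(1:2, 2:3), "at least 3")
  expect_error(sma_fit(rep(1, 5), rnorm(5)), "variance")
  expect_error(sma_fit(rnorm(5), rep(2, 5)), "variance")
})

test_that("tidy and glance expose the SMA fit as tibbles", {
  fit <- sma_fit(1:8, (1:8) * 1.5 + rnorm(8, 0, 0.1))
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_equal(td$term, c("slope", "intercept"))
  gl <- glance(fit)
  expect_equal(gl$n, 8)
})

test_that("duplicated groups give a zero slope-difference statistic and p = 1", {
  set.seed(9)
  x <- runif(20); y <- 2 * x + rnorm(20, 0, 0.2)
  st <- sma_slope_test(x, y, x, y)
  expect_equal(st$statistic, 0)
  expect_equal(st$p_value, 1)
})

test_that("clearly different slopes are detected with very small p", {
  set.seed(10)
  x1 <- runif(100, 1, 10); y1 <- 1 * x1 + rnorm(100, 0, 0.1)
  x2 <- runif(100, 1, 10); y2 <- 3 * x2 + rnorm(100, 0, 0.1)
  st <- sma_slope_test(x1, y1, x2, y2)
  expect_lt(st$p_value, 0.001)
  expect_equal(st$slope1, 1, tolerance = 0.05)
  expect_equal(st$slope2, 3, tolerance = 0.15)
  # permutation variant agrees on the strong effect
  set.seed(11)
  stp <- sma_slope_test(x1, y1, x2, y2, method = "permutation", n_perm = 199)
  expect_lt(stp$p_value, 0.02)
})

test_that("slope-difference test holds its size on iid bivariate data", {
  # two groups from identical lines plus identical noise laws
  set.seed(12)
  B <- 500
  rej <- 0
  for (i in seq_len(B)) {
    x1 <- runif(30, 0, 15); y1 <- 2 + 0.5 * x1 + rnorm(30)
    x2 <- runif(30, 0, 15); y2 <- 2 + 0.5 * x2 + rnorm(30)
    rej <- rej + (sma_slope_test(x1, y1, x2, y2)$p_value < 0.05)
  }
  band <- qbinom(c(0.025, 0.975), B, 0.05)
  expect_gte(rej, band[1])
  expect_lte(rej, band[2])
})

test_that("gazettement rates split decadal differences at the establishment decade", {
  traj <- tibble::tibble(
    site_id = "a",
    year = c(1900L, 1910L, 1920L, 1930L),
    pct_converted = c(0, 10, 20, 30)
  )
  r <- gazettement_rates(traj, c(a = 1920L))
  expect_equal(r$pre_rate, 10)
  expect_equal(r$post_rate, 10)
  expect_equal(r$n_decades_pre, 2L)
  expect_equal(r$n_decades_post, 1L)

  flat <- traj; flat$pct_converted <- rep(5, 4)
  rf <- gazettement_rates(flat, c(a = 1920L))
  expect_equal(rf$pre_rate, 0)
  expect_equal(rf$post_rate, 0)

  # establishment in a non-decadal year rounds up: 1911 -> decade 1920
  r2 <- gazettement_rates(traj, c(a = 1911L))
  expect_equal(r2$establishment_decade, 1920L)
  expect_equal(r2$n_decades_pre, 2L)
})

test_that("sites without both pre and post decades are excluded with reasons", {
  traj <- tibble::tibble(
    site_id = rep(c("first", "last", "nodate", "after", "mid"), each = 3),
    year = rep(c(1900L, 1910L, 1920L), 5),
    pct_converted = rep(c(0, 5, 9), 5)
  )
  est <- c(first = 1900L, last = 1920L, nodate = NA_integer_,
           after = 1950L, mid = 1910L)
  r <- gazettement_rates(traj, est)
  r <- r[match(c("first", "last", "nodate", "after", "mid"), r$site_id), ]
  # est at the first year leaves no pre decade; at the last year no post
  expect_equal(r$included, c(FALSE, FALSE, FALSE, FALSE, TRUE))
  expect_match(r$exclusion_reason[1], "no pre- or no post")
  expect_match(r$exclusion_reason[2], "no pre- or no post")
  expect_match(r$exclusion_reason[3], "missing establishment")
  expect_match(r$exclusion_reason[4], "after the series")
  expect_equal(r$pre_rate[5], 5)
  expect_equal(r$post_rate[5], 4)
})

test_that("paired t matches the textbook formula and rejects degenerate input", {
  set.seed(14)
  pre <- rnorm(30, 1, 0.5); post <- rnorm(30, 0.8, 0.5)
  res <- paired_t(pre, post)
  o <- oracle_paired_t(pre, post)
  expect_equal(res$statistic, o$t, tolerance = 1e-12)
  expect_equal(res$df, o$df)
  expect_equal(res$p_value, o$p, tolerance = 1e-12)
  expect_equal(res$mean_difference, mean(pre - post), tolerance = 1e-12)

  expect_error(paired_t(c(2, 4, 6), c(1, 3, 5)), "zero variance")
  expect_error(paired_t(c(1, 2), c(1, 2)), "zero variance")
  expect_error(paired_t(1:3, 1:4), "equal length")
})

test_that("size scaling is exactly unity under proportional conversion", {
  set.seed(15)
  area <- 10^runif(50, 0.5, 3)
  per_site <- tibble::tibble(area_km2 = area, pct_converted = 25)
  fit <- size_scaling(per_site)
  expect_equal(fit$slope, 1, tolerance = 1e-12)
  expect_false(fit$ci_excludes_unity)

  # conversion fraction declining with size -> slope below 1, CI excludes 1
  pct <- 100 * 10^(-0.4 - 0.35 * log10(area) + rnorm(50, 0, 0.08))
  fit2 <- size_scaling(tibble::tibble(area_km2 = area, pct_converted = pct))
  expect_lt(fit2$slope, 1)
  expect_true(fit2$ci_excludes_unity)
  expect_lt(fit2$p_value, 0.001)

  expect_error(size_scaling(per_site[1:2, ]), "at least 3")
})

test_that("zero-converted sites are excluded from the log-log fit and counted", {
  per_site <- tibble::tibble(area_km2 = c(10, 20, 40, 80, 160),
                             pct_converted = c(10, 10, 10, 10, 0))
  fit <- size_scaling(per_site)
  expect_equal(fit$n, 4)
  expect_equal(fit$n_excluded_zero, 1)
})

test_that("conversion histogram bins are half-open with a closed top bin", {
  h <- conversion_histogram(c(5, 15, 95))
  expect_equal(h$n, c(1, 1, 0, 0, 0, 0, 0, 0, 0, 1))
  h100 <- conversion_histogram(rep(100, 7))
  expect_equal(h100$n[10], 7)
  expect_equal(sum(h100$n), 7)
  # boundary values fall in the bin they open
  hb <- conversion_histogram(c(0, 10, 50))
  expect_equal(hb$n[c(1, 2, 6)], c(1, 1, 1))

  set.seed(16)
  u <- runif(1000, 0, 100)
  expect_equal(sum(conversion_histogram(u)$n), 1000)
  expect_equal(attr(conversion_histogram(u), "n_above_half"), sum(u > 50))

  expect_error(conversion_histogram(c(5, 105)), "0, 100")
  expect_error(conversion_histogram(c(-1, 5)), "0, 100")
})

test_that("quantile profile splits equal counts and spreads the remainder low", {
  set.seed(17)
  per_site <- tibble::tibble(
    site_id = sprintf("s%02d", 1:22),
    area_km2 = 10^runif(22, 0, 3),
    pct_converted = runif(22, 0, 100)
  )
  qp <- quantile_profile(per_site, k = 11)
  expect_equal(nrow(qp), 11)
  expect_true(all(qp$n == 2))
  expect_true(all(diff(qp$area_min) >= 0))

  # n = 25, k = 11 -> three groups of 3 (smallest areas), eight of 2
  ps25 <- tibble::tibble(site_id = sprintf("t%02d", 1:25),
                         area_km2 = 1:25, pct_converted = 50)
  qp25 <- quantile_profile(ps25, k = 11)
  expect_equal(qp25$n, c(3, 3, 3, rep(2, 8)))
  expect_true(all(qp25$mean_pct == 50))
  expect_true(all(qp25$se_pct == 0))

  # monotone decreasing conversion with size -> monotone group means
  mono <- tibble::tibble(site_id = sprintf("m%02d", 1:22),
                         area_km2 = 1:22, pct_converted = 100 - (1:22) * 3)
  expect_true(all(diff(quantile_profile(mono, 11)$mean_pct) < 0))

  expect_error(quantile_profile(per_site, k = 1), ">= 2")
  expect_error(quantile_profile(per_site[1:5, ], k = 11), "at least k")
})
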