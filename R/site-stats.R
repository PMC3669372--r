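# Per-site descriptive statistics: size-conversion scaling, the conversion
# histogram, and the size-quantile profile.

#' Size-conversion scaling (log-log SMA)
#'
#' SMA fit of `log10(converted area within site)` on `log10(site area)`. A
#' slope of exactly 1 means conversion is proportionally equal across sizes;
#' a slope below 1 with a confidence interval excluding unity means larger
#' sites have proportionally less of their land converted. Sites with zero
#' converted area cannot enter a log-log fit and are excluded (their count is
#' reported).
#'
#' @param per_site tibble with `area_km2` and `pct_converted` (one row per
#'   site), e.g. from [per_site_summary()].
#' @param confidence confidence level for the slope interval.
#' @return an `sma_fit` with extra fields `n_excluded_zero` (sites dropped
#'   for zero converted area) and `ci_excludes_unity`, and a unity-slope test
#'   (`statistic`, `p_value`).
#' @export
size_scaling <- function(per_site, confidence = 0.95) {
  ok <- !is.na(per_site$area_km2) & !is.na(per_site$pct_converted) &
    per_site$area_km2 > 0
  d <- per_site[ok, , drop = FALSE]
  conv_area <- d$area_km2 * d$pct_converted / 100
  nz <- conv_area > 0
  if (sum(nz) < 3) rlang::abort("size scaling needs at least 3 sites with nonzero converted area")
  fit <- sma_fit(log10(d$area_km2[nz]), log10(conv_area[nz]),
                 confidence = confidence, null_slope = 1,
                 xlab = "log10(site area km^2)",
                 ylab = "log10(converted area km^2)")
  fit$n_excluded_zero <- sum(!nz)
  fit$ci_excludes_unity <- fit$ci_low > 1 || fit$ci_high < 1
  fit
}

#' Histogram of per-site conversion levels
#'
#' Counts sites per conversion bin over `[0, 100]` percent. Bins are
#' half-open `[lo, hi)` with the top bin closed at 100, so a fully converted
#' site lands in the last bin.
#'
#' @param per_site_pct numeric vector of per-site percent converted, in
#'   `[0, 100]`.
#' @param bin_width bin width in percentage points (must divide 100).
#' @return tibble `bin_lower`, `bin_upper`, `n`, with attribute
#'   `"n_above_half"`: the number of sites with more than 50% converted.
#' @export
conversion_histogram <- function(per_site_pct, bin_width = 10) {
  if (any(is.na(per_site_pct))) rlang::abort("per-site percentages contain NA")
  if (any(per_site_pct < 0 | per_site_pct > 100)) {
    rlang::abort("per-site percentages must lie in [0, 100]")
  }
  if (100 %% bin_width != 0) rlang::abort("bin_width must divide 100")
  nb <- 100 %/% bin_width
  idx <- pmin(floor(per_site_pct / bin_width) + 1, nb) # 100 -> top bin
  out <- tibble::tibble(
    bin_lower = (seq_len(nb) - 1) * bin_width,
    bin_upper = seq_len(nb) * bin_width,
    n = tabulate(idx, nbins = nb)
  )
  attr(out, "n_above_half") <- sum(per_site_pct > 50)
  out
}

#' Mean conversion per site-size quantile group
#'
#' Ranks sites by area and splits them into `k` equal-count groups, the
#' remainder spread one extra site each over the smallest-area groups; ties
#' across a boundary are broken by stable `site_id` order. Reports the mean
#' and standard error of percent converted per group.
#'
#' @param per_site tibble with `area_km2`, `pct_converted` and optionally
#'   `site_id` (used for stable tie-breaking).
#' @param k number of quantile groups (>= 2, <= number of sites).
#' @return tibble: `group`, `n`, `area_min`, `area_max`, `mean_pct`,
#'   `se_pct`.
#' @export
quantile_profile <- function(per_site, k = 11) {
  n <- nrow(per_site)
  if (k < 2) rlang::abort("k must be >= 2")
  if (n < k) rlang::abort("need at least k sites")
  ord <- if ("site_id" %in% names(per_site)) {
    order(per_site$area_km2, per_site$site_id)
  } else {
    order(per_site$area_km2)
  }
  d <- per_site[ord, , drop = FALSE]
  sizes <- rep(n %/% k, k)
  extra <- n %% k
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  grp <- rep(seq_len(k), times = sizes)
  d$group <- grp
  dplyr::summarise(
    dplyr::group_by(d, .data$group),
    n = dplyr::n(),
    area_min = min(.data$area_km2),
    area_max = max(.data$area_km2),
    mean_pct = mean(.data$pct_converted),
    se_pct = stats::sd(.data$pct_converted) / sqrt(dplyr::n()),
    .groups = "drop"
  )
}
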