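# Pre/post-gazettement conversion rates and their paired comparison.

#' Pre- and post-gazettement conversion rates per site
#'
#' Splits each site's decadal percent-converted trajectory at its
#' establishment decade (the first decade year at or after the establishment
#' year). Consecutive decadal differences up to and including the
#' establishment decade are pre-gazettement; later differences are
#' post-gazettement. The establishment decade's own increment counts as pre:
#' conversion during that decade largely predates protection taking force.
#' Rates are in percentage points per decade (differences are rescaled if the
#' series spacing is not 10 years). Sites lacking at least one pre and one
#' post difference, or with an undefined trajectory, are excluded with a
#' reason.
#'
#' @param trajectories per-site trajectory tibble from
#'   [per_site_trajectory()] (`site_id`, `year`, `pct_converted`).
#' @param establishment_years named numeric vector (names = site_id) or a
#'   register tibble with `site_id` and `establishment_year`.
#' @return tibble: `site_id`, `establishment_year`, `establishment_decade`,
#'   `pre_rate`, `post_rate`, `n_decades_pre`, `n_decades_post`, `included`,
#'   `exclusion_reason`.
#' @export
gazettement_rates <- function(trajectories, establishment_years) {
  if (is.data.frame(establishment_years)) {
    est <- stats::setNames(establishment_years$establishment_year,
                           establishment_years$site_id)
  } else {
    est <- establishment_years
  }
  years <- sort(unique(trajectories$year))
  if (length(years) < 3) rlang::abort("need at least 3 decades to split pre/post")

  per_site <- split(trajectories, trajectories$site_id)
  ids <- names(per_site)
  n <- length(ids)
  est_year <- rep(NA_integer_, n); est_dec <- rep(NA_integer_, n)
  pre_rate <- rep(NA_real_, n); post_rate <- rep(NA_real_, n)
  n_pre <- integer(n); n_post <- integer(n)
  reason <- rep(NA_character_, n)

  for (s in seq_len(n)) {
    tr <- per_site[[s]]
    tr <- tr[order(tr$year), , drop = FALSE]
    ey <- unname(est[ids[s]])
    if (is.null(ey) || is.na(ey)) {
      reason[s] <- "missing establishment year"
      next
    }
    est_year[s] <- as.integer(ey)
    if (anyNA(tr$pct_converted)) {
      reason[s] <- "undefined trajectory (no land area)"
      next
    }
    dec <- establishment_decade(ey, tr$year)
    est_dec[s] <- dec
    if (is.na(dec)) {
      reason[s] <- "established after the series"
      next
    }
    diffs <- diff(tr$pct_converted) / diff(tr$year) * 10
    end_year <- tr$year[-1]
    is_pre <- end_year <= dec
    n_pre[s] <- sum(is_pre)
    n_post[s] <- sum(!is_pre)
    if (n_pre[s] == 0L || n_post[s] == 0L) {
      reason[s] <- "no pre- or no post-gazettement decades"
      next
    }
    pre_rate[s] <- mean(diffs[is_pre])
    post_rate[s] <- mean(diffs[!is_pre])
  }
  tibble::tibble(
    site_id = ids, establishment_year = est_year,
    establishment_decade = est_dec,
    pre_rate = pre_rate, post_rate = post_rate,
    n_decades_pre = n_pre, n_decades_post = n_post,
    included = !is.na(pre_rate) & !is.na(post_rate),
    exclusion_reason = reason
  )
}

#' Paired t-test on pre- vs post-gazettement rates
#'
#' Classical paired t-test on `pre - post` (wraps [stats::t.test()]), with
#' `df = n - 1`. A positive mean difference means conversion slowed after
#' gazettement.
#'
#' @param pre,post numeric vectors of equal length (n >= 2).
#' @return object of class `paired_test`: `statistic`, `df`, `p_value`,
#'   `mean_difference`, `n`.
#' @export
paired_t <- function(pre, post) {
  if (length(pre) != length(post)) rlang::abort("pre and post must have equal length")
  if (length(pre) < 2) rlang::abort("paired t-test needs at least 2 pairs")
  d <- pre - post
  if (stats::sd(d) == 0) {
    rlang::abort("paired differences have zero variance; t statistic undefined")
  }
  ht <- stats::t.test(pre, post, paired = TRUE)
  structure(
    list(statistic = unname(ht$statistic), df = unname(ht$parameter),
         p_value = ht$p.value, mean_difference = unname(ht$estimate),
         n = length(pre)),
    class = "paired_test"
  )
}

#' @export
print.paired_test <- function(x, ...) {
  cat(sprintf(
    "<paired_test> mean difference %.4f (n = %d): t = %.3f, df = %d, p = %.4g\n",
    x$mean_difference, x$n, x$statistic, x$df, x$p_value
  ))
  invisible(x)
}

#' @rdname paired_t
#' @param x a `paired_test` object (for `tidy`).
#' @param ... unused.
#' @export
tidy.paired_test <- function(x, ...) {
  tibble::tibble(
    estimate = x$mean_difference, statistic = x$statistic,
    parameter = x$df, p.value = x$p_value, n = x$n
  )
}
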