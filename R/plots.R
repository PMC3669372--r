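# ggplot2 displays for the main result types.

#' Plot the inside/outside conversion trajectory
#'
#' @param traj tibble from [trajectory()].
#' @return a ggplot.
#' @export
plot_trajectory <- function(traj) {
  long <- tidyr::pivot_longer(
    traj[, c("year", "pct_converted_inside", "pct_converted_outside")],
    -"year", names_to = "zone", values_to = "pct_converted",
    names_pattern = "pct_converted_(.*)"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$year, y = .data$pct_converted,
                                     colour = .data$zone, shape = .data$zone)) +
    ggplot2::geom_point(size = 2, na.rm = TRUE) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::labs(x = "Year", y = "% of land converted", colour = NULL,
                  shape = NULL) +
    ggplot2::theme_minimal()
}

#' Plot the per-site conversion histogram
#'
#' @param hist_counts tibble from [conversion_histogram()].
#' @return a ggplot.
#' @export
plot_conversion_histogram <- function(hist_counts) {
  hist_counts$mid <- (hist_counts$bin_lower + hist_counts$bin_upper) / 2
  ggplot2::ggplot(hist_counts, ggplot2::aes(x = .data$mid, y = .data$n)) +
    ggplot2::geom_col(width = diff(hist_counts$mid[1:2]) * 0.9,
                      fill = "grey30") +
    ggplot2::labs(x = "% of site converted", y = "Number of sites") +
    ggplot2::theme_minimal()
}

#' Plot mean conversion per site-size quantile group
#'
#' @param profile tibble from [quantile_profile()].
#' @return a ggplot.
#' @export
plot_quantile_profile <- function(profile) {
  ggplot2::ggplot(profile, ggplot2::aes(x = .data$group, y = .data$mean_pct)) +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$mean_pct - .data$se_pct,
      ymax = .data$mean_pct + .data$se_pct
    )) +
    ggplot2::scale_x_continuous(breaks = profile$group) +
    ggplot2::labs(x = "Site-size quantile (small to large)",
                  y = "Mean % converted (+/- 1 SE)") +
    ggplot2::theme_minimal()
}

#' @describeIn sma_fit scatter plot with the SMA line and its confidence band
#'   on the slope.
#' @param object an `sma_fit` (for `autoplot`).
#' @export
autoplot.sma_fit <- function(object, ...) {
  d <- tibble::tibble(x = object$x, y = object$y)
  xm <- mean(object$x); ym <- mean(object$y)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         colour = "firebrick") +
    ggplot2::geom_abline(slope = object$ci_low,
                         intercept = ym - object$ci_low * xm,
                         linetype = "dashed", colour = "firebrick") +
    ggplot2::geom_abline(slope = object$ci_high,
                         intercept = ym - object$ci_high * xm,
                         linetype = "dashed", colour = "firebrick") +
    ggplot2::labs(x = object$xlab, y = object$ylab) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
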