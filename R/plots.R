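#' Plot a fitted detection function over the distance histogram
#'
#' @param fit A `detection_fit`.
#' @param distances_m Optional distances to histogram behind the curve.
#' @param bins Histogram bins (default 12).
#' @return A ggplot object.
#' @export
plot_detection <- function(fit, distances_m = NULL, bins = 12) {
  g <- detection_function(fit)
  curve <- tibble::tibble(x = seq(0, fit$truncation_w_m, length.out = 200))
  curve$gx <- g(curve$x)
  p <- ggplot2::ggplot(curve, ggplot2::aes(x = .data$x, y = .data$gx))
  if (!is.null(distances_m)) {
    h <- tibble::tibble(d = distances_m[distances_m <= fit$truncation_w_m])
    p <- p + ggplot2::geom_histogram(
      data = h,
      ggplot2::aes(x = .data$d, y = ggplot2::after_stat(density) /
                     max(ggplot2::after_stat(density))),
      bins = bins, inherit.aes = FALSE, fill = "grey80", colour = "grey50")
  }
  p + ggplot2::geom_line(linewidth = 1) +
    ggplot2::labs(x = "Perpendicular distance (m)",
                  y = "Detection probability g(x)",
                  title = sprintf("ESW %.1f m, mean p %.2f",
                                  fit$esw_m, fit$p_bar)) +
    ggplot2::theme_minimal()
}

#' Plot per-stratum density estimates with confidence limits
#'
#' @param density Tibble from [density_by_stratum()].
#' @return A ggplot object.
#' @export
plot_density <- function(density) {
  ggplot2::ggplot(density,
                  ggplot2::aes(x = factor(.data$year),
                               y = .data$ind_density_km2,
                               colour = .data$stratum)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$lcl,
                                          ymax = .data$ucl),
                             position = ggplot2::position_dodge(0.3)) +
    ggplot2::labs(x = "Survey year", y = "Individuals / km²",
                  colour = "Stratum") +
    ggplot2::theme_minimal()
}

#' Plot the bootstrap distribution of the mean nest decay time
#'
#' @param object A `decay_estimate`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.decay_estimate <- function(object, ...) {
  df <- tibble::tibble(mean_days = object$boot_means[
    is.finite(object$boot_means)])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mean_days)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey80", colour = "grey40") +
    ggplot2::geom_vline(xintercept = c(object$ci_low_days,
                                       object$mean_days,
                                       object$ci_high_days),
                        linetype = c(2, 1, 2)) +
    ggplot2::labs(x = "Mean nest decay time (days)", y = "Replicates") +
    ggplot2::theme_minimal()
}

#' Plot the fitted seasonal fruit-availability curve per forest
#'
#' @param object A `seasonal_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.seasonal_fit <- function(object, ...) {
  d <- object$data
  d$fitted <- predict(object$model)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$date, colour = .data$forest)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$y), alpha = 0.6) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted)) +
    ggplot2::labs(x = "Date", y = "Transformed fruit index",
                  colour = "Forest") +
    ggplot2::theme_minimal()
}

#' Plot the autocovariate bandwidth likelihood profile
#'
#' @param profile Tibble with `sd_km` (or `sd_s_km`/`sd_t_days`) and
#'   `loglik`, as returned by [optimize_bandwidth()] or
#'   [optimize_two_bandwidths()].
#' @return A ggplot object.
#' @export
plot_bandwidth_profile <- function(profile) {
  if ("sd_km" %in% names(profile)) {
    ggplot2::ggplot(profile, ggplot2::aes(x = .data$sd_km,
                                          y = .data$loglik)) +
      ggplot2::geom_line() + ggplot2::geom_point() +
      ggplot2::scale_x_log10() +
      ggplot2::labs(x = "Kernel SD (km)", y = "log-likelihood") +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(profile,
                    ggplot2::aes(x = .data$sd_s_km, y = .data$sd_t_days,
                                 fill = .data$loglik)) +
      ggplot2::geom_tile() +
      ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
      ggplot2::labs(x = "Spatial SD (km)", y = "Temporal SD (days)",
                    fill = "logLik") +
      ggplot2::theme_minimal()
  }
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
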