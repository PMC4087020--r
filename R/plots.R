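#' Plot a Rubingh mixed-micelle analysis
#'
#' Experimental, ideal (Clint) and pure-component cmc values against
#' temperature, with the interaction parameter in a second panel when a
#' `temperature_C` column is available.
#'
#' @param object A `rubingh_analysis` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.rubingh_analysis <- function(object, ...) {
  if (!"temperature_C" %in% names(object)) {
    object <- dplyr::mutate(object, temperature_C = dplyr::row_number())
  }
  long <- tidyr::pivot_longer(
    dplyr::select(tibble::as_tibble(object), "temperature_C",
                  "cmc1_mM", "cmc2_mM", "cmc_mix_mM", "cmc_ideal_mM"),
    -"temperature_C", names_to = "series", values_to = "cmc_mM")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$temperature_C,
                                     y = .data$cmc_mM,
                                     colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "temperature (°C)", y = "cmc (mM)",
                  colour = NULL,
                  title = "Mixed-micelle cmc: experiment vs ideal mixing")
}

#' Plot a Boltzmann titration fit
#' @param object A `boltzmann_fit`.
#' @param ... Unused.
#' @return A ggplot object with the data, the fitted sigmoid and the cmc.
#' @exportS3Method ggplot2::autoplot
autoplot.boltzmann_fit <- function(object, ...) {
  grid <- tibble::tibble(x = seq(min(object$data$x), max(object$data$x),
                                 length.out = 200))
  grid$y <- object$a2 + (object$a1 - object$a2) /
    (1 + exp((grid$x - object$x0) / object$dx))
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid, colour = "steelblue") +
    ggplot2::geom_vline(xintercept = object$cmc, linetype = 2) +
    ggplot2::labs(x = "concentration (mM)", y = "response",
                  title = sprintf("Boltzmann fit: cmc = %.3g mM", object$cmc))
}

#' Plot a segmented-line breakpoint fit
#' @param object A `breakpoint_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.breakpoint_fit <- function(object, ...) {
  p <- ggplot2::ggplot(object$data, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "concentration (mM)", y = "response")
  if (object$has_breakpoint) {
    d1 <- dplyr::filter(object$data, .data$x <= object$breakpoint)
    d2 <- dplyr::filter(object$data, .data$x >= object$breakpoint)
    p <- p +
      ggplot2::geom_abline(intercept = object$intercept_pre,
                           slope = object$slope_pre, colour = "steelblue") +
      ggplot2::geom_abline(intercept = object$intercept_post,
                           slope = object$slope_post, colour = "firebrick") +
      ggplot2::geom_vline(xintercept = object$breakpoint, linetype = 2) +
      ggplot2::labs(title = sprintf("Breakpoint at %.3g mM", object$breakpoint))
  } else {
    p <- p + ggplot2::geom_smooth(method = "lm", formula = y ~ x,
                                  se = FALSE, colour = "steelblue") +
      ggplot2::labs(title = "No breakpoint detected")
  }
  p
}

#' Plot a blocked time series
#' @param object A `blocked_series`.
#' @param ... Unused.
#' @return A ggplot object with the raw series, block means and the
#'   window mean +/- sd band.
#' @exportS3Method ggplot2::autoplot
autoplot.blocked_series <- function(object, ...) {
  ggplot2::ggplot(object$series, ggplot2::aes(x = .data$time,
                                              y = .data$value)) +
    ggplot2::annotate("rect", xmin = object$window_us[1],
                      xmax = object$window_us[2],
                      ymin = object$mean - object$sd,
                      ymax = object$mean + object$sd,
                      alpha = 0.15, fill = "steelblue") +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::geom_point(data = object$blocks,
                        ggplot2::aes(x = .data$block_start,
                                     y = .data$block_mean),
                        colour = "steelblue") +
    ggplot2::geom_hline(yintercept = object$mean, linetype = 2) +
    ggplot2::labs(x = "time (µs)", y = "value",
                  title = sprintf("window mean %.3g ± %.3g",
                                  object$mean, object$sd))
}

#' Plot a cluster-size distribution
#' @param object A `size_distribution` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.size_distribution <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$size,
                                       y = .data$frequency)) +
    ggplot2::geom_col(width = 0.9, fill = "steelblue") +
    ggplot2::labs(x = "cluster size (molecules)", y = "frequency",
                  title = "Cluster-size distribution")
}

#' Plot a radial bead distribution
#' @param object A `radial_profile` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.radial_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$r, y = .data$density)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "distance from cluster COM (Å)", y = "density",
                  title = paste("Radial distribution:",
                                attr(object, "selector")))
}

#' Plot an orientation-angle distribution
#' @param object An `angle_profile` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.angle_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$theta,
                                       y = .data$frequency)) +
    ggplot2::geom_col(width = diff(object$theta[1:2]) * 0.95,
                      fill = "steelblue") +
    ggplot2::labs(x = expression(Theta ~ "(degrees)"), y = "frequency",
                  title = "SDS orientation inside micelles")
}
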