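#' Tidy a Boltzmann sigmoid fit
#'
#' @param x A `boltzmann_fit` from [fit_boltzmann()].
#' @param ... Unused.
#' @return A tibble with one row per parameter (`a1`, `a2`, `x0`, `dx`)
#'   and columns `term`, `estimate`.
#' @exportS3Method generics::tidy
tidy.boltzmann_fit <- function(x, ...) {
  tibble::tibble(term = c("a1", "a2", "x0", "dx"),
                 estimate = c(x$a1, x$a2, x$x0, x$dx))
}

#' @exportS3Method generics::glance
#' @rdname tidy.boltzmann_fit
glance.boltzmann_fit <- function(x, ...) {
  tibble::tibble(cmc = x$cmc, rss = x$rss, n = x$n,
                 sigma = sqrt(x$rss / (x$n - 4)))
}

#' Tidy a segmented-line breakpoint fit
#'
#' @param x A `breakpoint_fit` from [fit_breakpoint()].
#' @param ... Unused.
#' @return A tibble with one row per parameter.
#' @exportS3Method generics::tidy
tidy.breakpoint_fit <- function(x, ...) {
  tibble::tibble(
    term = c("breakpoint", "slope_pre", "slope_post",
             "intercept_pre", "intercept_post", "binding_fraction"),
    estimate = c(x$breakpoint, x$slope_pre, x$slope_post,
                 x$intercept_pre, x$intercept_post, x$binding_fraction)
  )
}

#' @exportS3Method generics::glance
#' @rdname tidy.breakpoint_fit
glance.breakpoint_fit <- function(x, ...) {
  tibble::tibble(has_breakpoint = x$has_breakpoint,
                 breakpoint = x$breakpoint,
                 binding_fraction = x$binding_fraction,
                 rss_segmented = x$rss_segmented,
                 rss_linear = x$rss_linear,
                 p_value = x$p_value, n = x$n)
}

#' Tidy a blocked time series
#'
#' @param x A `blocked_series` from [block_series()].
#' @param ... Unused.
#' @return The per-block tibble (`block_start`, `block_mean`, `n`).
#' @exportS3Method generics::tidy
tidy.blocked_series <- function(x, ...) x$blocks

#' @exportS3Method generics::glance
#' @rdname tidy.blocked_series
glance.blocked_series <- function(x, ...) {
  tibble::tibble(mean = x$mean, sd = x$sd, n_samples = nrow(x$series),
                 n_blocks = nrow(x$blocks), block_ns = x$block_ns,
                 window_start = x$window_us[1], window_end = x$window_us[2])
}
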