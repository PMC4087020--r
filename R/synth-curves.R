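#' Specification of a synthetic measurement curve
#'
#' @param kind `"titration"`, `"conductivity"` or `"tension"`.
#' @param true_params Named list of ground-truth model parameters.
#'   Titration: `a1`, `a2`, `x0`, `dx` (Boltzmann sigmoid). Conductivity:
#'   either `breakpoint`, `slope_pre`, `slope_post`, `intercept`
#'   (continuous two-segment line) or `slope`, `intercept` (single line,
#'   the breakpoint-free case). Tension: `breakpoint` (mM), `slope_pre`,
#'   `slope_post`, `intercept` on the (log10 concentration, tension) scale.
#' @param noise_sd Standard deviation of the additive Gaussian noise on the
#'   response, in response units (>= 0).
#' @param n_points Number of points (>= 6).
#' @param x_range Concentration range `(min, max)` in mM.
#' @param seed Integer seed making the curve reproducible.
#' @return A list of class `curve_spec`.
#' @export
curve_spec <- function(kind = c("titration", "conductivity", "tension"),
                       true_params, noise_sd = 0, n_points = 30,
                       x_range = c(1, 10), seed = 1L) {
  kind <- match.arg(kind)
  if (n_points < 6L) abort("`n_points` must be at least 6.")
  if (!is.finite(noise_sd) || noise_sd < 0) abort("`noise_sd` must be >= 0.")
  if (length(x_range) != 2L || x_range[1] <= 0 || x_range[2] <= x_range[1]) {
    abort("`x_range` must be an increasing positive (min, max) pair.")
  }
  structure(list(kind = kind, true_params = true_params,
                 noise_sd = noise_sd, n_points = as.integer(n_points),
                 x_range = x_range, seed = as.integer(seed)),
            class = "curve_spec")
}

curve_model <- function(spec, x) {
  p <- spec$true_params
  if (spec$kind == "titration") {
    stopifnot(all(c("a1", "a2", "x0", "dx") %in% names(p)))
    p$a2 + (p$a1 - p$a2) / (1 + exp((x - p$x0) / p$dx))
  } else if (spec$kind == "conductivity") {
    if (!is.null(p$breakpoint)) {
      y_bp <- p$intercept + p$slope_pre * p$breakpoint
      ifelse(x <= p$breakpoint,
             p$intercept + p$slope_pre * x,
             y_bp + p$slope_post * (x - p$breakpoint))
    } else {
      p$intercept + p$slope * x
    }
  } else { # tension: linear segments in log10 concentration
    lx <- log10(x)
    if (!is.null(p$breakpoint)) {
      lb <- log10(p$breakpoint)
      y_bp <- p$intercept + p$slope_pre * lb
      ifelse(lx <= lb,
             p$intercept + p$slope_pre * lx,
             y_bp + p$slope_post * (lx - lb))
    } else {
      p$intercept + p$slope * lx
    }
  }
}

#' Generate a synthetic measurement curve with known ground truth
#'
#' Evaluates the model implied by the spec on an evenly spaced
#' concentration grid and adds Gaussian noise. Identical specs (including
#' seeds) give bit-identical curves.
#'
#' @param spec A [curve_spec()].
#' @return A [measurement_curve()] whose `truth` attribute carries
#'   `spec$true_params`.
#' @export
generate_curve <- function(spec) {
  if (!inherits(spec, "curve_spec")) abort("`spec` must be a curve_spec.")
  x <- seq(spec$x_range[1], spec$x_range[2], length.out = spec$n_points)
  y0 <- curve_model(spec, x)
  y <- with_preserved_seed(spec$seed, y0 + rnorm(length(x), 0, spec$noise_sd))
  measurement_curve(x, y, kind = spec$kind, truth = spec$true_params)
}

# run code under a given seed without disturbing the caller's RNG stream
with_preserved_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  code
}
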