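#' Construct a measurement curve
#'
#' Wraps a raw (concentration, response) series in a validated container.
#' The response may be a pyrene I1/I3 fluorescence ratio (`titration`),
#' a specific conductivity in uS/cm (`conductivity`) or a surface tension
#' in mN/m (`tension`).
#'
#' @param x Concentration series (mM), strictly increasing and positive.
#' @param y Response series, same length as `x`.
#' @param kind One of `"titration"`, `"conductivity"`, `"tension"`.
#' @param truth Optional list of ground-truth model parameters when the
#'   curve is synthetic (kept as an attribute, never used by the fitters).
#' @return A tibble of class `measurement_curve` with columns `x` and `y`
#'   and attributes `kind` and `truth`.
#' @export
measurement_curve <- function(x, y, kind = c("titration", "conductivity", "tension"),
                              truth = NULL) {
  kind <- match.arg(kind)
  if (length(x) != length(y)) abort("`x` and `y` must have the same length.")
  if (length(x) < 6L) abort("A measurement curve needs at least 6 points.")
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    abort("Curve values must be finite.")
  }
  if (any(x <= 0)) abort("Concentrations must be strictly positive.")
  if (any(diff(x) <= 0)) abort("Concentrations must be strictly increasing.")
  out <- tibble::tibble(x = as.numeric(x), y = as.numeric(y))
  attr(out, "kind") <- kind
  attr(out, "truth") <- truth
  class(out) <- c("measurement_curve", class(out))
  out
}

#' @export
print.measurement_curve <- function(x, ...) {
  cat("<measurement_curve> kind:", curve_kind(x), " points:", nrow(x), "\n")
  NextMethod()
}

curve_kind <- function(curve) attr(curve, "kind") %||% "titration"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fit a Boltzmann sigmoid to a fluorimetric titration curve
#'
#' Least-squares fit of the Boltzmann function
#' `y = a2 + (a1 - a2) / (1 + exp((x - x0) / dx))`
#' to an I1/I3 titration curve; `a1` is the pre-micellar plateau (low
#' concentration), `a2` the post-micellar plateau, `x0` the inflection
#' concentration and `dx` the transition width. The cmc is reported as the
#' inflection `x0`. Starting values are data-driven: plateaus from the first
#' and last quartiles of the response, `x0` from the steepest
#' finite-difference point.
#'
#' @param curve A `measurement_curve` of kind `"titration"` (or any data
#'   frame with `x` and `y` columns).
#' @return An object of class `boltzmann_fit`: a list with elements
#'   `a1`, `a2`, `x0`, `dx`, `cmc`, `rss`, `fitted`, `data` and `n`.
#' @details The fit is deterministic given the data (no internal
#'   randomness). Monotone-increasing titration data trigger a warning
#'   (unexpected orientation for pyrene I1/I3) but are still fitted.
#' @examples
#' cur <- generate_curve(curve_spec(kind = "titration",
#'   true_params = list(a1 = 1.8, a2 = 1.2, x0 = 4.07, dx = 0.3),
#'   noise_sd = 0, n_points = 30, x_range = c(1, 10), seed = 1))
#' fit_boltzmann(cur)$cmc
#' @export
fit_boltzmann <- function(curve) {
  if (inherits(curve, "measurement_curve") && curve_kind(curve) != "titration") {
    abort("`fit_boltzmann()` expects a titration curve.")
  }
  x <- curve$x
  y <- curve$y
  if (length(x) < 6L) abort("Boltzmann fitting needs at least 6 points.")
  n <- length(x)
  q <- max(2L, floor(n / 4))
  a1_0 <- mean(head(y, q))
  a2_0 <- mean(tail(y, q))
  if (a2_0 > a1_0) {
    warn("Titration response increases with concentration; expected the I1/I3 ratio to fall at micellisation.")
  }
  slopes <- diff(y) / diff(x)
  steep <- which.max(abs(slopes))
  x0_0 <- mean(x[steep + 0:1])
  span <- diff(range(x))
  # the transition width is the least certain start: try a ladder of guesses
  fit <- NULL
  last_err <- NULL
  for (dx_0 in span / c(10, 20, 5, 40, 3)) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ a2 + (a1 - a2) / (1 + exp((x - x0) / dx)),
        data = data.frame(x = x, y = y),
        start = list(a1 = a1_0, a2 = a2_0, x0 = x0_0, dx = dx_0),
        control = minpack.lm::nls.lm.control(maxiter = 500)
      ),
      error = function(e) {
        last_err <<- conditionMessage(e)
        NULL
      }
    )
    if (!is.null(fit)) break
  }
  if (is.null(fit)) {
    abort(paste0("Boltzmann fit did not converge: ", last_err))
  }
  cf <- coef(fit)
  a1 <- unname(cf["a1"]); a2 <- unname(cf["a2"])
  x0 <- unname(cf["x0"]); dxw <- unname(cf["dx"])
  # dx < 0 is the same curve with the plateaus swapped; normalise to dx > 0
  if (dxw < 0) {
    tmp <- a1; a1 <- a2; a2 <- tmp
    dxw <- -dxw
  }
  if (x0 < min(x) || x0 > max(x)) {
    warn("Fitted inflection lies outside the measured concentration range.")
  }
  structure(
    list(a1 = a1, a2 = a2, x0 = x0, dx = dxw, cmc = x0,
         rss = sum(resid(fit)^2), fitted = fitted(fit),
         data = tibble::tibble(x = x, y = y), n = n),
    class = "boltzmann_fit"
  )
}

#' @export
print.boltzmann_fit <- function(x, ...) {
  cat("Boltzmann sigmoid fit\n")
  cat(sprintf("  cmc (inflection x0): %.4g mM\n", x$cmc))
  cat(sprintf("  plateaus: %.4g -> %.4g, width dx = %.4g mM\n",
              x$a1, x$a2, x$dx))
  cat(sprintf("  rss = %.4g over %d points\n", x$rss, x$n))
  invisible(x)
}

#' Segmented-line breakpoint fit for conductivity or tension curves
#'
#' Grid search over candidate breakpoints (every interior data point with at
#' least `min_points` points on each side, plus the midpoints between
#' consecutive points), fitting independent least-squares lines to the two
#' segments. The segmented model is accepted only if an F-test against the
#' single-line fit gives `p < alpha` *and* the post/pre slope ratio differs
#' from 1 by more than `slope_tol`; otherwise the curve is declared
#' breakpoint-free (the conductivity signature of a micelle whose surface
#' charge is not neutralised by counterions). When a breakpoint is accepted
#' it is refined to the intersection of the two fitted lines, and the
#' counterion binding fraction `1 - slope_post/slope_pre` (clipped to
#' `[0, 1]`) is reported.
#'
#' @param curve A `measurement_curve` of kind `"conductivity"` or
#'   `"tension"` (or any data frame with `x` and `y`).
#' @param alpha Significance level of the segmented-vs-linear F-test.
#' @param slope_tol Minimum relative difference of the slope ratio from 1.
#' @param min_points Minimum number of points required on each side of a
#'   candidate breakpoint.
#' @return An object of class `breakpoint_fit`: a list with
#'   `has_breakpoint`, `breakpoint` (mM, `NA` when absent), `slope_pre`,
#'   `slope_post`, `intercept_pre`, `intercept_post`, `binding_fraction`
#'   (`NA` when absent), `rss_segmented`, `rss_linear`, `p_value`, `data`,
#'   `n`.
#' @export
fit_breakpoint <- function(curve, alpha = 0.05, slope_tol = 0.05,
                           min_points = 3L) {
  if (inherits(curve, "measurement_curve") &&
      !curve_kind(curve) %in% c("conductivity", "tension")) {
    abort("`fit_breakpoint()` expects a conductivity or tension curve.")
  }
  x <- curve$x
  y <- curve$y
  n <- length(x)
  if (n < 2L * min_points) {
    abort(sprintf("Breakpoint fitting needs at least %d points on each side of a candidate; got %d points total.",
                  min_points, n))
  }
  mids <- (head(x, -1) + tail(x, -1)) / 2
  candidates <- sort(unique(c(x[-c(1L, n)], mids)))
  candidates <- candidates[
    vapply(candidates, function(c0) {
      sum(x <= c0) >= min_points && sum(x > c0) >= min_points
    }, logical(1))
  ]
  if (!length(candidates)) {
    abort("No candidate breakpoint leaves enough points on both sides.")
  }
  fit_lin <- lm(y ~ x)
  rss_linear <- sum(resid(fit_lin)^2)
  best <- NULL
  for (c0 in candidates) {
    left <- x <= c0
    f1 <- lm(y ~ x, subset = left)
    f2 <- lm(y ~ x, subset = !left)
    rss <- sum(resid(f1)^2) + sum(resid(f2)^2)
    if (is.null(best) || rss < best$rss) {
      best <- list(rss = rss, c0 = c0,
                   b1 = unname(coef(f1)), b2 = unname(coef(f2)))
    }
  }
  rss_segmented <- best$rss
  slope_pre <- best$b1[2]
  slope_post <- best$b2[2]
  # F-test: segmented model has 4 parameters, the single line 2
  df2 <- n - 4L
  p_value <- if (rss_segmented <= .Machine$double.eps * max(1, rss_linear)) {
    if (rss_linear > rss_segmented * 1e6 + .Machine$double.eps) 0 else 1
  } else {
    Fstat <- ((rss_linear - rss_segmented) / 2) / (rss_segmented / df2)
    pf(Fstat, 2, df2, lower.tail = FALSE)
  }
  ratio <- slope_post / slope_pre
  has_bp <- is.finite(p_value) && p_value < alpha &&
    is.finite(ratio) && abs(ratio - 1) > slope_tol
  if (has_bp) {
    # refine: intersection of the two fitted lines
    bp <- (best$b2[1] - best$b1[1]) / (best$b1[2] - best$b2[2])
    if (!is.finite(bp) || bp < min(x) || bp > max(x)) bp <- best$c0
    binding <- min(max(1 - ratio, 0), 1)
  } else {
    bp <- NA_real_
    binding <- NA_real_
  }
  structure(
    list(has_breakpoint = has_bp, breakpoint = bp,
         slope_pre = slope_pre, slope_post = slope_post,
         intercept_pre = best$b1[1], intercept_post = best$b2[1],
         binding_fraction = binding,
         rss_segmented = rss_segmented, rss_linear = rss_linear,
         p_value = p_value, data = tibble::tibble(x = x, y = y), n = n),
    class = "breakpoint_fit"
  )
}

#' @export
print.breakpoint_fit <- function(x, ...) {
  cat("Segmented-line breakpoint fit\n")
  if (x$has_breakpoint) {
    cat(sprintf("  breakpoint (cmc): %.4g mM\n", x$breakpoint))
    cat(sprintf("  slopes: %.4g -> %.4g (binding fraction %.3f)\n",
                x$slope_pre, x$slope_post, x$binding_fraction))
  } else {
    cat("  no breakpoint detected (single-line behaviour)\n")
  }
  cat(sprintf("  rss segmented/linear: %.4g / %.4g, F-test p = %.3g\n",
              x$rss_segmented, x$rss_linear, x$p_value))
  invisible(x)
}

#' Extract the cmc from a raw measurement curve
#'
#' Dispatches on the curve kind: titration curves are fitted with the
#' Boltzmann sigmoid ([fit_boltzmann()]; cmc = inflection), conductivity
#' curves with the segmented-line breakpoint model ([fit_breakpoint()];
#' cmc = breakpoint), and tension curves with the same breakpoint model on
#' (log10 concentration, tension) — the standard gamma vs log c analysis —
#' with the breakpoint mapped back to concentration.
#'
#' @param curve A [measurement_curve()].
#' @param ... Passed on to the underlying fitter.
#' @return The fit object, with an element `cmc` (mM; `NA` when a
#'   breakpoint-based fit finds no transition).
#' @export
fit_cmc <- function(curve, ...) {
  kind <- curve_kind(curve)
  if (kind == "titration") {
    fit_boltzmann(curve, ...)
  } else if (kind == "conductivity") {
    fit <- fit_breakpoint(curve, ...)
    fit$cmc <- fit$breakpoint
    fit
  } else {
    logcur <- tibble::tibble(x = log10(curve$x), y = curve$y)
    fit <- fit_breakpoint(logcur, ...)
    fit$breakpoint <- if (is.na(fit$breakpoint)) NA_real_ else 10^fit$breakpoint
    fit$cmc <- fit$breakpoint
    fit$data <- tibble::tibble(x = curve$x, y = curve$y)
    # binding fraction is a conductivity concept; not meaningful for tension
    fit$binding_fraction <- NA_real_
    fit
  }
}
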