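#' Ideal mixed critical micelle concentration (Clint relation)
#'
#' Computes the cmc an ideally mixing binary surfactant system would have,
#' given the pure-component cmc values and the bulk mole fraction of
#' component 1: `1/cmc_id = alpha1/cmc1 + (1 - alpha1)/cmc2`. For an ideal
#' mixture the micellar pseudo-phase behaves as an ideal solution, so the
#' mixed cmc is the mole-fraction-weighted harmonic combination of the pure
#' cmc values.
#'
#' @param alpha1 Bulk mole fraction of component 1, in `[0, 1]`. Vectorised.
#' @param cmc1,cmc2 Pure-component critical micelle concentrations (mM),
#'   strictly positive. Vectorised.
#' @return Ideal mixed cmc in the same concentration units as `cmc1`/`cmc2`.
#' @examples
#' clint_cmc(0.5, 11.50, 11.98) # 11.74 mM at 25 degrees C
#' @seealso [rubingh_x1()], [interaction_parameter()], [rubingh_analysis()]
#' @export
clint_cmc <- function(alpha1, cmc1, cmc2) {
  check_cmc(cmc1, "cmc1")
  check_cmc(cmc2, "cmc2")
  if (any(!is.finite(alpha1)) || any(alpha1 < 0) || any(alpha1 > 1)) {
    abort("`alpha1` must be a mole fraction in [0, 1].")
  }
  1 / (alpha1 / cmc1 + (1 - alpha1) / cmc2)
}

#' Micellar mole fraction of component 1 (Rubingh regular solution theory)
#'
#' Solves the implicit regular-solution condition for the mole fraction `x1`
#' of component 1 inside the mixed micelle:
#' \deqn{x_1^2 \ln\frac{\alpha_1 c^{mix}}{x_1 c_1} =
#'       (1-x_1)^2 \ln\frac{(1-\alpha_1) c^{mix}}{(1-x_1) c_2}}
#' The root is located by Brent's method on the bracket
#' `(1e-6, 1 - 1e-6)`; the residual at the returned root is required to be
#' below `1e-10`.
#'
#' @inheritParams clint_cmc
#' @param cmc_mix Experimental cmc of the mixture (mM), strictly positive.
#' @param tol Convergence tolerance passed to [stats::uniroot()].
#' @return The micellar mole fraction `x1` in `(0, 1)`. Vectorised over the
#'   inputs.
#' @examples
#' rubingh_x1(0.5, 11.50, 11.98, 4.07) # ~0.503 at 25 degrees C
#' @export
rubingh_x1 <- function(alpha1, cmc1, cmc2, cmc_mix, tol = 1e-12) {
  n <- max(length(alpha1), length(cmc1), length(cmc2), length(cmc_mix))
  args <- vctrs_recycle(alpha1 = alpha1, cmc1 = cmc1, cmc2 = cmc2,
                        cmc_mix = cmc_mix, n = n)
  vapply(seq_len(n), function(i) {
    rubingh_x1_scalar(args$alpha1[i], args$cmc1[i], args$cmc2[i],
                      args$cmc_mix[i], tol = tol)
  }, numeric(1))
}

rubingh_x1_scalar <- function(alpha1, cmc1, cmc2, cmc_mix, tol = 1e-12) {
  check_cmc(c(cmc1, cmc2, cmc_mix), "cmc")
  if (!is.finite(alpha1) || alpha1 <= 0 || alpha1 >= 1) {
    abort("`alpha1` must lie strictly inside (0, 1) for a binary mixture.")
  }
  f <- function(x) rubingh_residual(x, alpha1, cmc1, cmc2, cmc_mix)
  eps <- 1e-6
  lo <- f(eps)
  hi <- f(1 - eps)
  if (!is.finite(lo) || !is.finite(hi) || sign(lo) == sign(hi)) {
    abort(paste0(
      "No physical solution: the Rubingh residual does not change sign on (",
      format(eps), ", ", format(1 - eps), ") for these inputs."
    ))
  }
  root <- uniroot(f, lower = eps, upper = 1 - eps, tol = tol,
                  maxiter = 2000L)
  if (abs(f(root$root)) > 1e-10) {
    abort("Rubingh root search did not converge: residual exceeds 1e-10.")
  }
  root$root
}

#' Residual of the Rubingh implicit equation
#'
#' The difference between the two equivalent regular-solution expressions for
#' the interaction parameter, multiplied through by the squared counter-terms.
#' It is zero exactly at the physical micellar composition.
#'
#' @inheritParams rubingh_x1
#' @param x1 Trial micellar mole fraction of component 1, in `(0, 1)`.
#' @return Residual value (dimensionless); vectorised over `x1`.
#' @export
rubingh_residual <- function(x1, alpha1, cmc1, cmc2, cmc_mix) {
  x1^2 * log(alpha1 * cmc_mix / (x1 * cmc1)) -
    (1 - x1)^2 * log((1 - alpha1) * cmc_mix / ((1 - x1) * cmc2))
}

#' Regular-solution interaction parameter between the two surfactants
#'
#' Evaluates `beta = ln(alpha1 * cmc_mix / (x1 * cmc1)) / (1 - x1)^2`.
#' A negative value signals synergism: net attractive interactions between
#' the unlike building units lower the mixed cmc below the ideal prediction.
#'
#' @inheritParams rubingh_x1
#' @param x1 Micellar mole fraction of component 1, typically from
#'   [rubingh_x1()]; must lie strictly inside `(0, 1)`.
#' @return Dimensionless interaction parameter. Vectorised.
#' @examples
#' x1 <- rubingh_x1(0.5, 11.50, 11.98, 4.07)
#' interaction_parameter(0.5, 4.07, 11.50, x1) # ~ -4.23
#' @export
interaction_parameter <- function(alpha1, cmc_mix, cmc1, x1) {
  check_cmc(cmc1, "cmc1")
  check_cmc(cmc_mix, "cmc_mix")
  if (any(!is.finite(x1)) || any(x1 <= 0) || any(x1 >= 1)) {
    abort("`x1` must lie strictly inside (0, 1) (division by (1 - x1)^2).")
  }
  if (any(!is.finite(alpha1)) || any(alpha1 <= 0) || any(alpha1 >= 1)) {
    abort("`alpha1` must lie strictly inside (0, 1).")
  }
  log(alpha1 * cmc_mix / (x1 * cmc1)) / (1 - x1)^2
}

#' Rubingh analysis of a table of mixed-micelle cmc records
#'
#' Takes one row per condition (typically per temperature) with the
#' pure-component and mixture cmc values, and appends the derived
#' regular-solution columns: the Clint ideal cmc, the micellar mole fraction
#' of component 1 from the Rubingh implicit equation, the interaction
#' parameter and a synergism flag (`beta12 < 0`).
#'
#' @param data A data frame with columns `cmc1_mM`, `cmc2_mM`, `cmc_mix_mM`
#'   and `alpha1` (one record per condition). A `temperature_C` column, if
#'   present, is used to identify records in error messages and plots.
#' @return A tibble of class `rubingh_analysis`: the input columns plus
#'   `cmc_ideal_mM`, `x1`, `beta12` and `synergistic`, in the input row
#'   order.
#' @examples
#' tbl <- nacasds_cmc_table()
#' rubingh_analysis(tbl)
#' @export
rubingh_analysis <- function(data) {
  required <- c("cmc1_mM", "cmc2_mM", "cmc_mix_mM", "alpha1")
  missing <- setdiff(required, names(data))
  if (length(missing)) {
    abort(paste0("`data` is missing required column(s): ",
                 paste(missing, collapse = ", ")))
  }
  if (nrow(data) == 0L) abort("`data` must contain at least one record.")
  ids <- if ("temperature_C" %in% names(data)) {
    paste0(data$temperature_C, " degC")
  } else {
    paste0("row ", seq_len(nrow(data)))
  }
  out <- purrr::map(seq_len(nrow(data)), function(i) {
    rec <- data[i, ]
    res <- tryCatch(
      {
        cid <- clint_cmc(rec$alpha1, rec$cmc1_mM, rec$cmc2_mM)
        x1 <- rubingh_x1(rec$alpha1, rec$cmc1_mM, rec$cmc2_mM, rec$cmc_mix_mM)
        beta <- interaction_parameter(rec$alpha1, rec$cmc_mix_mM,
                                      rec$cmc1_mM, x1)
        tibble::tibble(cmc_ideal_mM = cid, x1 = x1, beta12 = beta,
                       synergistic = beta < 0)
      },
      error = function(e) {
        abort(paste0("Rubingh analysis failed for record ", ids[i], ": ",
                     conditionMessage(e)))
      }
    )
    res
  })
  res <- dplyr::bind_cols(tibble::as_tibble(data), dplyr::bind_rows(out))
  class(res) <- c("rubingh_analysis", class(res))
  res
}

#' Temperature-dependent cmc table for the NaCA + SDS 1:1 binary mixture
#'
#' Packaged reference table of fluorimetric and tensiometric critical micelle
#' concentrations of pure sodium cholate (component 1), pure sodium
#' dodecylsulphate (component 2) and their equimolar mixture between 0 and
#' 50 degrees C, with the reported experimental uncertainties.
#'
#' @return A tibble with columns `temperature_C`, `cmc1_mM`, `cmc1_sd_mM`,
#'   `cmc2_mM`, `cmc2_sd_mM`, `cmc_mix_mM`, `cmc_mix_sd_mM` (fluorimetric
#'   mixture cmc), `cmc_mix_tens_mM`, `cmc_mix_tens_sd_mM` and `alpha1`.
#' @export
nacasds_cmc_table <- function() {
  path <- system.file("extdata", "nacasds_cmc_table.csv",
                      package = "micellemix", mustWork = TRUE)
  readr::read_csv(path, show_col_types = FALSE)
}

#' @exportS3Method generics::glance
#' @rdname glance.rubingh_analysis
glance.rubingh_analysis <- function(x, ...) {
  tibble::tibble(
    n = nrow(x),
    mean_beta12 = mean(x$beta12),
    sd_beta12 = sd(x$beta12),
    mean_x1 = mean(x$x1),
    all_synergistic = all(x$synergistic)
  )
}

#' One-row summary of a Rubingh mixed-micelle analysis
#'
#' @param x A `rubingh_analysis` tibble from [rubingh_analysis()].
#' @param ... Unused.
#' @return A one-row tibble with the record count, mean and spread of the
#'   interaction parameter, the mean micellar composition, and whether every
#'   record was synergistic.
#' @name glance.rubingh_analysis
NULL

check_cmc <- function(x, what) {
  if (any(!is.finite(x)) || any(x <= 0)) {
    abort(paste0("`", what, "` values must be finite and strictly positive."))
  }
  invisible(x)
}

vctrs_recycle <- function(..., n) {
  args <- list(...)
  lapply(args, function(a) {
    if (length(a) == n) a
    else if (length(a) == 1L) rep(a, n)
    else abort("Inputs must have length 1 or a common length.")
  })
}
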