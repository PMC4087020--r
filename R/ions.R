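#' Classify sodium counterions as condensed or free
#'
#' A Na+ ion is *condensed* when its minimum-image distance to any
#' negatively charged surfactant bead (the SO3 head of SDS or the OCO
#' carboxylate of cholate) is strictly less than `cutoff`; otherwise it is
#' free. Condensed counterions partially neutralise the micelle surface
#' charge and are the simulation-side counterpart of the conductivity
#' breakpoint analysis.
#'
#' @param frame A [cg_frame()].
#' @param cutoff Condensation distance criterion (Angstrom, default 7).
#' @return An object of class `ion_partition`: a one-row tibble with
#'   columns `time`, `n_condensed`, `n_free`, `n_total`
#'   (`n_condensed + n_free == n_total` always). A frame without Na+
#'   returns an all-zero partition with a warning.
#' @export
classify_ions <- function(frame, cutoff = 7) {
  if (!is.finite(cutoff) || cutoff <= 0) {
    abort("`cutoff` must be a positive distance.")
  }
  b <- frame$beads
  na_beads <- b[b$kind == "NA", c("x", "y", "z")]
  if (!nrow(na_beads)) {
    warn("Frame contains no Na+ ions; returning an empty partition.")
    out <- tibble::tibble(time = frame$time, n_condensed = 0L, n_free = 0L,
                          n_total = 0L)
    class(out) <- c("ion_partition", class(out))
    return(out)
  }
  charged <- b[b$kind %in% c("SDS", "CA") & b$charge < 0, c("x", "y", "z")]
  if (!nrow(charged)) {
    abort("Frame contains no negatively charged surfactant beads.")
  }
  na_m <- as.matrix(na_beads)
  ch_m <- as.matrix(charged)
  condensed <- vapply(seq_len(nrow(na_m)), function(i) {
    d <- sweep(ch_m, 2, na_m[i, ])
    d <- min_image_disp(d, frame$box)
    any(rowSums(d^2) < cutoff^2)
  }, logical(1))
  out <- tibble::tibble(time = frame$time,
                        n_condensed = sum(condensed),
                        n_free = sum(!condensed),
                        n_total = length(condensed))
  attr(out, "condensed") <- which(condensed)
  class(out) <- c("ion_partition", class(out))
  out
}

#' Condensed/free counterion time series with block averaging
#'
#' Applies [classify_ions()] to every frame in the analysis window and
#' block-averages the condensed and free counts with the same convention as
#' [noc_series()].
#'
#' @inheritParams noc_series
#' @return An object of class `ion_series`: a list with `partition` (tibble
#'   of per-frame counts), and [block_series()] objects `condensed` and
#'   `free`.
#' @export
ion_series <- function(traj, cutoff = 7, block_ns = 100,
                       window_us = c(0.6, 10)) {
  frames <- frames_in_window(traj, window_us)
  parts <- dplyr::bind_rows(lapply(frames, classify_ions, cutoff = cutoff))
  structure(
    list(partition = parts,
         condensed = block_series(parts$time, parts$n_condensed,
                                  block_ns = block_ns, window_us = window_us),
         free = block_series(parts$time, parts$n_free,
                             block_ns = block_ns, window_us = window_us)),
    class = "ion_series"
  )
}

#' @export
print.ion_series <- function(x, ...) {
  cat(sprintf("<ion_series> %d frames: condensed %.2f +/- %.2f, free %.2f +/- %.2f (of %d Na+)\n",
              nrow(x$partition), x$condensed$mean, x$condensed$sd,
              x$free$mean, x$free$sd, x$partition$n_total[1]))
  invisible(x)
}
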