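#' Identify surfactant clusters in a frame
#'
#' Two or more surfactant molecules belong to the same cluster when they are
#' connected through pairs whose closest-bead minimum-image distance is
#' strictly less than `cutoff` (default 7 Angstrom). Counterions and water
#' are never clustered. Single unaggregated molecules count as clusters of
#' size 1. Cluster labels are assigned deterministically in order of first
#' molecule appearance.
#'
#' @param frame A [cg_frame()] containing at least one surfactant molecule.
#' @param cutoff Closest-bead distance criterion (Angstrom), positive.
#'   Pairs at exactly the cutoff are not joined.
#' @return An object of class `cluster_assignment`: a list with
#'   `frame_time`, `labels` (tibble: `molecule_id`, `kind`, `cluster`),
#'   `n_clusters`, and `clusters` (tibble: `cluster`, `size`, `n_sds`,
#'   `n_ca`, `sds_fraction`).
#' @export
find_clusters <- function(frame, cutoff = 7) {
  if (!is.finite(cutoff) || cutoff <= 0) {
    abort("`cutoff` must be a positive distance.")
  }
  mols <- frame_molecules(frame, kinds = c("SDS", "CA"))
  n <- length(mols$coords)
  if (!n) abort("Frame contains no surfactant molecules.")
  dmat <- closest_bead_matrix(frame, kinds = c("SDS", "CA"))
  adj <- dmat < cutoff
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership
  # relabel deterministically by first molecule appearance
  labels <- match(comp, unique(comp))
  lab_tbl <- tibble::tibble(molecule_id = mols$molecule_id,
                            kind = mols$kind, cluster = labels)
  clusters <- dplyr::summarise(
    dplyr::group_by(lab_tbl, .data$cluster),
    size = dplyr::n(),
    n_sds = sum(.data$kind == "SDS"),
    n_ca = sum(.data$kind == "CA"),
    sds_fraction = .data$n_sds / .data$size,
    .groups = "drop"
  )
  structure(
    list(frame_time = frame$time, labels = lab_tbl,
         n_clusters = max(labels), clusters = clusters),
    class = "cluster_assignment"
  )
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("<cluster_assignment> t = %g us: %d molecules in %d cluster(s); sizes: %s\n",
              x$frame_time, nrow(x$labels), x$n_clusters,
              paste(sort(x$clusters$size, decreasing = TRUE), collapse = " ")))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.cluster_assignment <- function(x, ...) x$labels

#' @exportS3Method generics::glance
glance.cluster_assignment <- function(x, ...) {
  tibble::tibble(
    time = x$frame_time,
    n_molecules = nrow(x$labels),
    n_clusters = x$n_clusters,
    largest = max(x$clusters$size),
    mean_sds_fraction = mean(x$clusters$sds_fraction)
  )
}

frames_in_window <- function(traj, window_us) {
  if (length(window_us) != 2L || window_us[2] <= window_us[1]) {
    abort("`window_us` must be an increasing (start, end) pair in microseconds.")
  }
  times <- trajectory_times(traj)
  keep <- times >= window_us[1] & times <= window_us[2]
  if (!any(keep)) abort("No frames fall inside the analysis window.")
  traj$frames[keep]
}

window_assignments <- function(traj, cutoff, window_us) {
  lapply(frames_in_window(traj, window_us), find_clusters, cutoff = cutoff)
}

#' Block-average a time series
#'
#' Divides a (time, value) series into consecutive non-overlapping blocks of
#' fixed length and reports per-block means together with the overall mean
#' and standard deviation over the window. Block averaging suppresses serial
#' correlation when quoting uncertainties of trajectory observables.
#'
#' @param time Times in microseconds.
#' @param value Observable values at those times.
#' @param block_ns Block length in nanoseconds (default 100 ns).
#' @param window_us Analysis window `(start, end)` in microseconds.
#' @return An object of class `blocked_series`: list with `series` (tibble
#'   `time`, `value` restricted to the window), `blocks` (tibble
#'   `block_start`, `block_mean`, `n`), `mean`, `sd`, `block_ns`,
#'   `window_us`. A trailing partial block is dropped with a warning.
#' @export
block_series <- function(time, value, block_ns = 100,
                         window_us = c(min(time), max(time))) {
  if (length(window_us) != 2L || window_us[2] <= window_us[1]) {
    abort("`window_us` must be an increasing (start, end) pair.")
  }
  block_us <- block_ns / 1e3
  if (window_us[2] - window_us[1] < block_us) {
    abort("Analysis window is shorter than one block.")
  }
  keep <- time >= window_us[1] & time <= window_us[2]
  if (!any(keep)) abort("No samples fall inside the analysis window.")
  t <- time[keep]; v <- value[keep]
  idx <- floor((t - window_us[1]) / block_us)
  n_full <- floor((window_us[2] - window_us[1]) / block_us + 1e-9)
  partial <- idx >= n_full
  if (any(partial)) {
    warn("Dropping samples in a trailing partial block.")
    t <- t[!partial]; v <- v[!partial]; idx <- idx[!partial]
  }
  blocks <- dplyr::summarise(
    dplyr::group_by(tibble::tibble(idx = idx, v = v), .data$idx),
    block_mean = mean(.data$v), n = dplyr::n(), .groups = "drop"
  )
  blocks <- dplyr::mutate(blocks,
                          block_start = window_us[1] + .data$idx * block_us)
  structure(
    list(series = tibble::tibble(time = t, value = v),
         blocks = blocks[, c("block_start", "block_mean", "n")],
         mean = mean(v), sd = sd(v),
         block_ns = block_ns, window_us = window_us),
    class = "blocked_series"
  )
}

#' @export
print.blocked_series <- function(x, ...) {
  cat(sprintf("<blocked_series> %d samples in [%g, %g] us, %d blocks of %g ns\n",
              nrow(x$series), x$window_us[1], x$window_us[2],
              nrow(x$blocks), x$block_ns))
  cat(sprintf("  mean = %.4g, sd = %.4g\n", x$mean, x$sd))
  invisible(x)
}

#' Number-of-clusters time series with block averaging
#'
#' Computes the number of surfactant clusters (NOC) in every frame and
#' block-averages the series over the analysis window (default 0.6-10 us,
#' the post-assembly regime, with 100 ns blocks).
#'
#' @param traj A [cg_trajectory()].
#' @param cutoff Closest-bead cluster criterion (Angstrom).
#' @param block_ns Block length in nanoseconds.
#' @param window_us Analysis window `(start, end)` in microseconds.
#' @return A [block_series()] object whose `series` holds the per-frame NOC.
#' @export
noc_series <- function(traj, cutoff = 7, block_ns = 100,
                       window_us = c(0.6, 10)) {
  asg <- window_assignments(traj, cutoff, window_us)
  times <- vapply(asg, function(a) a$frame_time, numeric(1))
  noc <- vapply(asg, function(a) a$n_clusters, numeric(1))
  block_series(times, noc, block_ns = block_ns, window_us = window_us)
}

#' Cluster-size distribution pooled over an analysis window
#'
#' @inheritParams noc_series
#' @return A tibble of class `size_distribution` with columns `size`,
#'   `count` and `frequency` (normalised to sum to 1 over the pooled
#'   cluster observations).
#' @export
size_distribution <- function(traj, cutoff = 7, window_us = c(0.6, 10)) {
  asg <- window_assignments(traj, cutoff, window_us)
  sizes <- unlist(lapply(asg, function(a) a$clusters$size))
  tab <- table(sizes)
  out <- tibble::tibble(size = as.integer(names(tab)),
                        count = as.integer(tab),
                        frequency = as.integer(tab) / length(sizes))
  class(out) <- c("size_distribution", class(out))
  out
}

#' SDS content of clusters as a function of cluster size
#'
#' For every observed cluster size, the mean and standard deviation of the
#' per-cluster SDS mole fraction `x2`, pooled over the frames of the
#' analysis window. The overall mean weights every cluster equally
#' (averaged over all aggregates), and is attached as attributes
#' `global_mean` / `global_sd`. Sizes observed only once report `NA` for
#' the spread, not 0.
#'
#' @inheritParams noc_series
#' @return A tibble of class `sds_content` with columns `size`, `mean_x2`,
#'   `sd_x2` and `n_clusters`.
#' @export
sds_content_by_size <- function(traj, cutoff = 7, window_us = c(0.6, 10)) {
  asg <- window_assignments(traj, cutoff, window_us)
  cl <- dplyr::bind_rows(lapply(asg, function(a) a$clusters))
  out <- dplyr::summarise(
    dplyr::group_by(cl, .data$size),
    mean_x2 = mean(.data$sds_fraction),
    sd_x2 = ifelse(dplyr::n() > 1L, sd(.data$sds_fraction), NA_real_),
    n_clusters = dplyr::n(),
    .groups = "drop"
  )
  attr(out, "global_mean") <- mean(cl$sds_fraction)
  attr(out, "global_sd") <- if (nrow(cl) > 1L) sd(cl$sds_fraction) else NA_real_
  class(out) <- c("sds_content", class(out))
  out
}

#' Unaggregated-monomer statistics over an analysis window
#'
#' The fraction of molecule-frames found in size-1 clusters, with the
#' breakdown of those free monomers by surfactant kind.
#'
#' @inheritParams noc_series
#' @return A one-row tibble with columns `frac_free` (fraction of
#'   molecule-frames unaggregated), `frac_free_sds`, `frac_free_ca`
#'   (composition of the free monomers; `NA` when none are free),
#'   `n_molecule_frames` and `n_free`.
#' @export
free_monomer_stats <- function(traj, cutoff = 7, window_us = c(0.6, 10)) {
  asg <- window_assignments(traj, cutoff, window_us)
  lab <- dplyr::bind_rows(lapply(asg, function(a) {
    sizes <- a$clusters$size[match(a$labels$cluster, a$clusters$cluster)]
    dplyr::mutate(a$labels, free = sizes == 1L)
  }))
  n_free <- sum(lab$free)
  tibble::tibble(
    frac_free = n_free / nrow(lab),
    frac_free_sds = if (n_free) sum(lab$free & lab$kind == "SDS") / n_free else NA_real_,
    frac_free_ca = if (n_free) sum(lab$free & lab$kind == "CA") / n_free else NA_real_,
    n_molecule_frames = nrow(lab),
    n_free = n_free
  )
}
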