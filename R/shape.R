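#' Gyration tensor and relative shape anisotropy of a bead set
#'
#' The (mass-unweighted) gyration tensor is the mean outer product of the
#' bead positions about their centre of mass. Its sorted eigenvalues
#' `lambda_x >= lambda_y >= lambda_z` describe the principal extents, and
#' the relative shape anisotropy
#' \deqn{K^2 = 1 - 3\frac{\lambda_x\lambda_y + \lambda_y\lambda_z +
#'   \lambda_x\lambda_z}{(\lambda_x+\lambda_y+\lambda_z)^2}}
#' is 0 for spherically symmetric arrangements and 1 for collinear ones.
#' Coordinates must already be unwrapped (no periodic splits); use
#' [unwrap_coords()] first for clusters read from a periodic box.
#'
#' @param coords Matrix of bead coordinates (rows = beads, >= 2 rows),
#'   Angstrom, unwrapped.
#' @return An object of class `gyration_result`: a list with `lambda`
#'   (length-3, descending, Angstrom^2), `k2`, `rg2` (squared radius of
#'   gyration) and `n_beads`. All beads coincident is the degenerate point
#'   case and reports `k2 = 0`.
#' @examples
#' gyration_anisotropy(cbind(1:5, 0, 0))$k2 # collinear -> 1
#' @export
gyration_anisotropy <- function(coords) {
  coords <- rbind(coords)
  if (nrow(coords) < 2L) abort("Need at least 2 beads for a gyration tensor.")
  if (any(!is.finite(coords))) abort("Coordinates must be finite.")
  centred <- sweep(coords, 2, colMeans(coords))
  s <- crossprod(centred) / nrow(coords)
  lambda <- sort(eigen(s, symmetric = TRUE, only.values = TRUE)$values,
                 decreasing = TRUE)
  lambda[lambda < 0 & lambda > -1e-12] <- 0
  tr <- sum(lambda)
  k2 <- if (tr <= .Machine$double.eps) {
    0 # all beads coincident: degenerate point, defined as spherical
  } else {
    1 - 3 * (lambda[1] * lambda[2] + lambda[2] * lambda[3] +
               lambda[1] * lambda[3]) / tr^2
  }
  k2 <- min(max(k2, 0), 1)
  structure(list(lambda = lambda, k2 = k2, rg2 = tr, n_beads = nrow(coords)),
            class = "gyration_result")
}

#' @export
print.gyration_result <- function(x, ...) {
  cat(sprintf("<gyration_result> lambda = (%.4g, %.4g, %.4g) A^2, K^2 = %.4f\n",
              x$lambda[1], x$lambda[2], x$lambda[3], x$k2))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.gyration_result <- function(x, ...) {
  tibble::tibble(lambda_x = x$lambda[1], lambda_y = x$lambda[2],
                 lambda_z = x$lambda[3], k2 = x$k2, rg2 = x$rg2,
                 n_beads = x$n_beads)
}

# Unwrapped bead coordinates of one cluster; reference is the first bead of
# the cluster's first molecule, so periodic splits cannot corrupt the COM.
cluster_bead_coords <- function(frame, assignment, cluster_id) {
  ids <- assignment$labels$molecule_id[assignment$labels$cluster == cluster_id]
  b <- frame$beads[frame$beads$molecule_id %in% ids, c("x", "y", "z")]
  unwrap_coords(as.matrix(b), frame$box)
}

#' Mean shape anisotropy as a function of cluster size
#'
#' For every cluster in every frame of the analysis window, K^2 is computed
#' from the unwrapped bead coordinates of all member molecules, then
#' averaged per cluster size.
#'
#' @inheritParams noc_series
#' @return A tibble of class `shape_by_size` with columns `size`,
#'   `mean_k2`, `sd_k2` (`NA` for sizes observed once) and `n_clusters`.
#' @export
shape_by_size <- function(traj, cutoff = 7, window_us = c(0.6, 10)) {
  frames <- frames_in_window(traj, window_us)
  rows <- dplyr::bind_rows(lapply(frames, function(fr) {
    a <- find_clusters(fr, cutoff = cutoff)
    dplyr::bind_rows(lapply(seq_len(a$n_clusters), function(ci) {
      co <- cluster_bead_coords(fr, a, ci)
      k2 <- if (nrow(co) >= 2L) gyration_anisotropy(co)$k2 else NA_real_
      tibble::tibble(size = a$clusters$size[a$clusters$cluster == ci], k2 = k2)
    }))
  }))
  out <- dplyr::summarise(
    dplyr::group_by(rows, .data$size),
    mean_k2 = mean(.data$k2, na.rm = TRUE),
    sd_k2 = ifelse(dplyr::n() > 1L, sd(.data$k2, na.rm = TRUE), NA_real_),
    n_clusters = dplyr::n(),
    .groups = "drop"
  )
  class(out) <- c("shape_by_size", class(out))
  out
}

#' Radial distribution of selected beads about their cluster's centre of mass
#'
#' Histogram of the distances of the selected beads from the (unwrapped)
#' centre of mass of their cluster, pooled over frames and clusters of at
#' least `min_size` molecules, normalised to sum to 1 over the bins. Each
#' selector is normalised independently.
#'
#' @inheritParams noc_series
#' @param kind Molecule kind of the selected beads (`"SDS"` or `"CA"`).
#' @param bead Bead name within that kind (e.g. `"SO3"`, `"C4"`, `"OCO"`).
#' @param bin_width Histogram bin width in Angstrom (default 1).
#' @param min_size Minimum cluster size contributing (default 20).
#' @param r_weighted Divide each bin by the shell volume `4 pi r^2 dr`
#'   before normalising (number-density convention) instead of the raw
#'   histogram.
#' @return A tibble of class `radial_profile` with columns `r` (bin
#'   midpoint, Angstrom), `count` and `density`.
#' @export
radial_profile <- function(traj, kind, bead, cutoff = 7,
                           window_us = c(0.6, 10), bin_width = 1,
                           min_size = 20, r_weighted = FALSE) {
  if (!bead %in% bead_topology(kind)$bead) {
    abort(sprintf("Bead `%s` does not exist in the %s topology.", bead, kind))
  }
  frames <- frames_in_window(traj, window_us)
  dists <- unlist(lapply(frames, function(fr) {
    a <- find_clusters(fr, cutoff = cutoff)
    big <- a$clusters$cluster[a$clusters$size >= min_size]
    unlist(lapply(big, function(ci) {
      ids <- a$labels$molecule_id[a$labels$cluster == ci]
      b <- fr$beads[fr$beads$molecule_id %in% ids, , drop = FALSE]
      co <- unwrap_coords(as.matrix(b[, c("x", "y", "z")]), fr$box)
      com <- colMeans(co)
      sel <- b$kind == kind & b$bead == bead
      if (!any(sel)) return(numeric(0))
      sqrt(rowSums(sweep(co[sel, , drop = FALSE], 2, com)^2))
    }))
  }))
  if (!length(dists)) {
    abort("Selector matched no beads in any qualifying cluster.")
  }
  edges <- seq(0, ceiling(max(dists) / bin_width) * bin_width + bin_width,
               by = bin_width)
  # left-closed bins: a bead exactly at a bin edge belongs to the outer bin
  h <- graphics::hist(dists, breaks = edges, plot = FALSE, right = FALSE)
  dens <- h$counts
  if (r_weighted) {
    shell <- 4 / 3 * pi * (edges[-1]^3 - head(edges, -1)^3)
    dens <- dens / shell
  }
  out <- tibble::tibble(r = h$mids, count = h$counts,
                        density = dens / sum(dens))
  attr(out, "selector") <- paste(kind, bead)
  attr(out, "n_beads") <- length(dists)
  class(out) <- c("radial_profile", class(out))
  out
}

#' Orientation-angle distribution of SDS molecules inside micelles
#'
#' For every SDS molecule in clusters of at least `min_size` molecules, the
#' angle Theta between the head-to-tail vector (SO3 -> C4) and the
#' head-to-centre vector (SO3 -> cluster centre of mass) is computed on the
#' unwrapped cluster. Theta close to 0 means the tail points along the
#' radius toward the micelle core; 180 degrees means it points outward.
#'
#' @inheritParams noc_series
#' @param min_size Minimum cluster size contributing (default 20).
#' @param bin_width Histogram bin width in degrees (default 5).
#' @return A tibble of class `angle_profile` with columns `theta` (bin
#'   midpoint, degrees in `[0, 180]`), `count` and `frequency` (sums to 1).
#'   The number of molecules skipped for a zero-length vector is attached
#'   as attribute `n_skipped`.
#' @export
orientation_angles <- function(traj, cutoff = 7, window_us = c(0.6, 10),
                               min_size = 20, bin_width = 5) {
  frames <- frames_in_window(traj, window_us)
  skipped <- 0L
  thetas <- unlist(lapply(frames, function(fr) {
    a <- find_clusters(fr, cutoff = cutoff)
    big <- a$clusters$cluster[a$clusters$size >= min_size]
    unlist(lapply(big, function(ci) {
      ids <- a$labels$molecule_id[a$labels$cluster == ci]
      b <- fr$beads[fr$beads$molecule_id %in% ids, , drop = FALSE]
      co <- unwrap_coords(as.matrix(b[, c("x", "y", "z")]), fr$box)
      com <- colMeans(co)
      sds_ids <- unique(b$molecule_id[b$kind == "SDS"])
      vapply(sds_ids, function(id) {
        so3 <- co[b$molecule_id == id & b$bead == "SO3", , drop = FALSE][1, ]
        c4 <- co[b$molecule_id == id & b$bead == "C4", , drop = FALSE][1, ]
        v1 <- c4 - so3
        v2 <- com - so3
        n1 <- sqrt(sum(v1^2)); n2 <- sqrt(sum(v2^2))
        if (n1 < 1e-9 || n2 < 1e-9) {
          skipped <<- skipped + 1L
          return(NA_real_)
        }
        acos(min(max(sum(v1 * v2) / (n1 * n2), -1), 1)) * 180 / pi
      }, numeric(1))
    }))
  }))
  thetas <- thetas[!is.na(thetas)]
  if (!length(thetas)) abort("No SDS molecules found in qualifying clusters.")
  edges <- seq(0, 180, by = bin_width)
  h <- graphics::hist(thetas, breaks = edges, plot = FALSE,
                      include.lowest = TRUE)
  out <- tibble::tibble(theta = h$mids, count = h$counts,
                        frequency = h$counts / sum(h$counts))
  attr(out, "n_skipped") <- skipped
  attr(out, "n_angles") <- length(thetas)
  class(out) <- c("angle_profile", class(out))
  out
}
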