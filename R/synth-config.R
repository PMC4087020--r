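#' Specification of a constructed micelle configuration
#'
#' Describes a single frame with fully known ground truth: a set of
#' micelles with given composition and geometry, free monomers, and a
#' planted partition of the counterions into condensed and free. Used to
#' round-trip-test the cluster, shape and ion analyses.
#'
#' @param clusters A list of cluster descriptions, each a list with
#'   `n_sds`, `n_ca`, `geometry` (`"sphere"` or `"rod"`) and optionally
#'   `radius` (Angstrom; for rods the cylinder radius). Defaults scale with
#'   the aggregate size.
#' @param free_sds,free_ca Numbers of unaggregated monomers.
#' @param n_na Number of Na+ ions; defaults to the total surfactant count
#'   (overall charge neutrality, one monovalent counterion per anionic
#'   surfactant).
#' @param planted_condensed How many Na+ to place within 7 Angstrom of a
#'   charged surfactant bead; the rest are placed beyond 10 Angstrom of
#'   every charged bead.
#' @param box Cubic box edge (Angstrom).
#' @param seed Integer seed.
#' @return A list of class `config_spec`.
#' @export
config_spec <- function(clusters = list(), free_sds = 0, free_ca = 0,
                        n_na = NULL, planted_condensed = 0, box = 200,
                        seed = 1L) {
  n_surf <- sum(vapply(clusters, function(cl) cl$n_sds + cl$n_ca,
                       numeric(1))) + free_sds + free_ca
  if (n_surf < 1) abort("The configuration must contain at least one surfactant.")
  if (is.null(n_na)) n_na <- n_surf
  if (planted_condensed > n_na) {
    abort("`planted_condensed` cannot exceed the number of Na+ ions.")
  }
  for (cl in clusters) {
    if (!is.null(cl$radius) && cl$radius >= box / 4) {
      abort("Cluster radii must be smaller than a quarter of the box edge.")
    }
    if (!cl$geometry %in% c("sphere", "rod")) {
      abort("Cluster geometry must be \"sphere\" or \"rod\".")
    }
  }
  structure(list(clusters = clusters, free_sds = free_sds,
                 free_ca = free_ca, n_na = as.integer(n_na),
                 planted_condensed = as.integer(planted_condensed),
                 box = box, seed = as.integer(seed)),
            class = "config_spec")
}

runif_sphere <- function(n, radius) {
  # uniform in a ball: direction on the sphere, radius ~ R * U^(1/3)
  v <- matrix(rnorm(3 * n), ncol = 3)
  v <- v / sqrt(rowSums(v^2))
  v * radius * runif(n)^(1 / 3)
}

# beads of one molecule as a compact random cloud about its centre
molecule_blob <- function(kind, centre, spread = 1.1) {
  topo <- bead_topology(kind)
  offs <- runif_sphere(nrow(topo), spread)
  tibble::tibble(kind = kind, bead = topo$bead,
                 x = centre[1] + offs[, 1],
                 y = centre[2] + offs[, 2],
                 z = centre[3] + offs[, 3])
}

# molecule-centre coordinates for one aggregate; connectivity under the
# 7 A closest-bead criterion is enforced by retry
sample_cluster_centres <- function(n, geometry, radius, link_cutoff = 7,
                                   blob_spread = 1.1, max_tries = 200L) {
  # two blobs of spread s around centres d apart can be up to d + 2s apart
  # at their closest beads; require the centre graph to connect below this
  centre_cut <- link_cutoff - 2 * blob_spread - 0.2
  for (try in seq_len(max_tries)) {
    if (geometry == "sphere") {
      ctr <- runif_sphere(n, radius)
      if (n == 1L) return(ctr)
      d <- as.matrix(stats::dist(ctr))
      g <- igraph::graph_from_adjacency_matrix(d < centre_cut,
                                               mode = "undirected")
      if (igraph::components(g)$no == 1L) return(ctr)
    } else {
      # rod: a directed random walk along a random axis whose step norms
      # stay below the linking cut, so the chain is connected by build
      axis <- rnorm(3); axis <- axis / sqrt(sum(axis^2))
      e1 <- rnorm(3); e1 <- e1 - sum(e1 * axis) * axis
      e1 <- e1 / sqrt(sum(e1^2))
      e2 <- c(axis[2] * e1[3] - axis[3] * e1[2],
              axis[3] * e1[1] - axis[1] * e1[3],
              axis[1] * e1[2] - axis[2] * e1[1])
      ctr <- matrix(0, n, 3)
      ok <- TRUE
      for (i in seq_len(n)[-1]) {
        a <- runif(1, 2.2, min(3.6, centre_cut - 0.6))
        jit_max <- sqrt(max(centre_cut^2 * 0.9 - a^2, 0.01))
        ang <- runif(1, 0, 2 * pi)
        jr <- runif(1, 0, jit_max)
        cand <- ctr[i - 1, ] + a * axis +
          jr * (cos(ang) * e1 + sin(ang) * e2)
        # keep the walk inside the cylinder radius
        rad_vec <- cand - sum(cand * axis) * axis
        rn <- sqrt(sum(rad_vec^2))
        if (rn > radius) cand <- cand - rad_vec * (1 - radius / rn)
        if (sqrt(sum((cand - ctr[i - 1, ])^2)) >= centre_cut) {
          ok <- FALSE
          break
        }
        ctr[i, ] <- cand
      }
      if (ok) return(sweep(ctr, 2, colMeans(ctr)))
    }
  }
  abort("Could not sample a connected aggregate; increase the density or retries.")
}

#' Build a configuration frame with known cluster and ion ground truth
#'
#' Places each requested aggregate (and each free monomer) in the box so
#' that distinct groups are separated by more than 14 Angstrom at their
#' closest beads, guaranteeing that [find_clusters()] at the default 7
#' Angstrom cutoff recovers exactly the planted partition; aggregates are
#' internally connected by construction. Exactly `planted_condensed` Na+
#' ions are placed within 7 Angstrom of a charged bead and the remainder
#' beyond 10 Angstrom of every charged bead, so [classify_ions()] recovers
#' the planted ion partition exactly.
#'
#' @param spec A [config_spec()].
#' @return A list with elements `frame` (a [cg_frame()]) and `truth`, a
#'   list with `labels` (tibble `molecule_id`, `kind`, `cluster`),
#'   `n_clusters`, `sizes`, `sds_fraction` per cluster, and
#'   `n_condensed`.
#' @export
build_configuration <- function(spec) {
  if (!inherits(spec, "config_spec")) abort("`spec` must be a config_spec.")
  with_preserved_seed(spec$seed, build_configuration_impl(spec))
}

build_configuration_impl <- function(spec) {
  box <- spec$box
  blob <- 1.1
  groups <- c(
    lapply(spec$clusters, function(cl) {
      n <- cl$n_sds + cl$n_ca
      radius <- cl$radius %||% if (cl$geometry == "sphere") {
        2.0 * n^(1 / 3) + 1
      } else 3.0
      extent <- if (cl$geometry == "sphere") radius + blob else {
        2.0 * n + radius + blob
      }
      list(kinds = c(rep("SDS", cl$n_sds), rep("CA", cl$n_ca)),
           geometry = cl$geometry, radius = radius, extent = extent)
    }),
    lapply(seq_len(spec$free_sds), function(i) {
      list(kinds = "SDS", geometry = "sphere", radius = 0.5,
           extent = 0.5 + blob)
    }),
    lapply(seq_len(spec$free_ca), function(i) {
      list(kinds = "CA", geometry = "sphere", radius = 0.5,
           extent = 0.5 + blob)
    })
  )
  if (max(vapply(groups, `[[`, numeric(1), "extent")) > box / 4) {
    abort("An aggregate is too large for the box (extent must be < box/4).")
  }
  # place group centres with pairwise clearance: closest beads of distinct
  # groups must exceed 14 A (twice the cluster cutoff)
  centres <- matrix(NA_real_, nrow = length(groups), ncol = 3)
  for (gi in seq_along(groups)) {
    placed <- FALSE
    for (try in seq_len(4000L)) {
      cand <- runif(3, 0, box)
      ok <- TRUE
      if (gi > 1L) {
        for (gj in seq_len(gi - 1L)) {
          dd <- minimum_image_distance(cand, centres[gj, ], box)
          clearance <- groups[[gi]]$extent + groups[[gj]]$extent + 15
          if (dd < clearance) { ok <- FALSE; break }
        }
      }
      if (ok) { centres[gi, ] <- cand; placed <- TRUE; break }
    }
    if (!placed) {
      abort("Infeasible packing: could not place all aggregates with the required clearance. Use a larger box or fewer/smaller aggregates.")
    }
  }
  # generate beads
  beads <- list()
  labels <- list()
  mol_id <- 0L
  for (gi in seq_along(groups)) {
    g <- groups[[gi]]
    n <- length(g$kinds)
    ctr <- if (n == 1L) {
      matrix(0, 1, 3)
    } else {
      sample_cluster_centres(n, g$geometry, g$radius, blob_spread = blob)
    }
    kinds <- sample(g$kinds) # shuffle composition within the aggregate
    for (mi in seq_len(n)) {
      mol_id <- mol_id + 1L
      mb <- molecule_blob(kinds[mi], centres[gi, ] + ctr[mi, ], spread = blob)
      mb$molecule_id <- mol_id
      beads[[length(beads) + 1L]] <- mb
      labels[[length(labels) + 1L]] <- tibble::tibble(
        molecule_id = mol_id, kind = kinds[mi], cluster = gi)
    }
  }
  surf <- dplyr::bind_rows(beads)
  truth_labels <- dplyr::bind_rows(labels)
  # counterions
  charged <- surf[paste(surf$kind, surf$bead) %in% c("SDS SO3", "CA OCO"),
                  c("x", "y", "z")]
  ch_m <- as.matrix(charged)
  na_rows <- list()
  n_cond <- spec$planted_condensed
  if (n_cond > 0L) {
    anchor <- sample(nrow(ch_m), n_cond, replace = TRUE)
    for (i in seq_len(n_cond)) {
      dir <- rnorm(3); dir <- dir / sqrt(sum(dir^2))
      pos <- ch_m[anchor[i], ] + dir * runif(1, 2.5, 6.0)
      na_rows[[length(na_rows) + 1L]] <- pos
    }
  }
  n_free_na <- spec$n_na - n_cond
  for (i in seq_len(n_free_na)) {
    placed <- FALSE
    for (try in seq_len(4000L)) {
      cand <- runif(3, 0, box)
      d <- min_image_disp(sweep(ch_m, 2, cand), box)
      if (all(rowSums(d^2) > 10^2)) {
        na_rows[[length(na_rows) + 1L]] <- cand
        placed <- TRUE
        break
      }
    }
    if (!placed) abort("Infeasible packing: could not place a free Na+ beyond 10 A of every charged bead.")
  }
  na_tbl <- if (length(na_rows)) {
    pos <- do.call(rbind, na_rows)
    tibble::tibble(kind = "NA", bead = "NA",
                   molecule_id = mol_id + seq_len(nrow(pos)),
                   x = pos[, 1], y = pos[, 2], z = pos[, 3])
  } else NULL
  frame <- cg_frame(dplyr::bind_rows(surf, na_tbl), box = box, time = 0)
  sizes <- as.integer(table(truth_labels$cluster))
  sds_fraction <- vapply(split(truth_labels$kind, truth_labels$cluster),
                         function(k) mean(k == "SDS"), numeric(1))
  list(frame = frame,
       truth = list(labels = truth_labels,
                    n_clusters = max(truth_labels$cluster),
                    sizes = sizes,
                    sds_fraction = unname(sds_fraction),
                    n_condensed = n_cond,
                    n_na = spec$n_na))
}
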