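# Independent brute-force oracles and small frame builders used across the
# suite. The oracles deliberately avoid the package's computational paths.

# minimum-image distance by explicit enumeration of all 27 periodic images
# (points are wrapped into the primary cell first, so one image shell is
# guaranteed to contain the nearest image)
bf_min_image <- function(p, q, box) {
  shifts <- as.matrix(expand.grid(sx = -1:1, sy = -1:1, sz = -1:1)) * box
  d <- (q %% box) - (p %% box)
  min(sqrt(rowSums(sweep(shifts, 2, d, `+`)^2)))
}

# closest-bead distance by exhaustive pair enumeration over 27 images
bf_closest_bead <- function(mol_a, mol_b, box) {
  best <- Inf
  for (i in seq_len(nrow(mol_a))) {
    for (j in seq_len(nrow(mol_b))) {
      best <- min(best, bf_min_image(mol_a[i, ], mol_b[j, ], box))
    }
  }
  best
}

# connected components via a plain union-find over the O(n^2) molecule pairs
bf_components <- function(coord_list, box, cutoff) {
  n <- length(coord_list)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (bf_closest_bead(coord_list[[i]], coord_list[[j]], box) < cutoff) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

# condensed/free partition by exhaustive distances
bf_classify_ions <- function(frame, cutoff = 7) {
  b <- frame$beads
  na_m <- as.matrix(b[b$kind == "NA", c("x", "y", "z")])
  ch_m <- as.matrix(b[b$kind %in% c("SDS", "CA") & b$charge < 0,
                      c("x", "y", "z")])
  vapply(seq_len(nrow(na_m)), function(i) {
    any(vapply(seq_len(nrow(ch_m)), function(j) {
      bf_min_image(na_m[i, ], ch_m[j, ], frame$box)
    }, numeric(1)) < cutoff)
  }, logical(1))
}

# a surfactant molecule whose beads sit in a tight cloud (spread = 0 puts
# every bead exactly at the centre, giving exact inter-molecule distances)
mol_cloud <- function(kind, centre, id, spread = 0) {
  topo <- bead_topology(kind)
  n <- nrow(topo)
  off <- if (spread > 0) {
    matrix(stats::runif(3 * n, -spread, spread), ncol = 3)
  } else {
    matrix(0, n, 3)
  }
  tibble::tibble(molecule_id = id, kind = kind, bead = topo$bead,
                 x = centre[1] + off[, 1], y = centre[2] + off[, 2],
                 z = centre[3] + off[, 3])
}

na_bead <- function(centre, id) {
  tibble::tibble(molecule_id = id, kind = "NA", bead = "NA",
                 x = centre[1], y = centre[2], z = centre[3])
}

# frame from a list of molecule tibbles
frame_of <- function(..., box = 200, time = 0) {
  cg_frame(dplyr::bind_rows(...), box = box, time = time)
}

# canonical form of a partition (for label-invariant comparisons)
partition_canon <- function(labels) match(labels, unique(labels))

# replicate one frame at several times to make a static trajectory
static_trajectory <- function(frame, times) {
  cg_trajectory(lapply(times, function(t) {
    f <- frame
    f$time <- t
    f
  }))
}
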