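#' Bead topology of a coarse-grained molecule kind
#'
#' The mixed-micelle system is built from three molecule kinds: sodium
#' dodecylsulphate mapped to 4 beads (tail C4, C2, C1 and the charged
#' sulphate head SO3), cholate mapped to 8 beads (steroid ring beads R1-R3
#' on the hydrophobic convex side, RO2, RO3, ROH on the hydrophilic concave
#' side, the C1 tail bead and the charged carboxylate OCO) and the Na+
#' counterion as a single charged bead. A single-bead water kind `W` is
#' provided for completeness but is not used by any analysis.
#'
#' @param kind One of `"SDS"`, `"CA"`, `"NA"`, `"W"`.
#' @return A tibble with columns `bead` (name, in chain order), `class`
#'   (`hydrophobic`, `hydrophilic` or `charged`) and `charge` (elementary
#'   units).
#' @export
bead_topology <- function(kind = c("SDS", "CA", "NA", "W")) {
  kind <- match.arg(kind)
  switch(kind,
    SDS = tibble::tibble(
      bead = c("C4", "C2", "C1", "SO3"),
      class = c("hydrophobic", "hydrophobic", "hydrophobic", "charged"),
      charge = c(0, 0, 0, -1)
    ),
    CA = tibble::tibble(
      bead = c("R1", "R2", "R3", "RO2", "RO3", "ROH", "C1", "OCO"),
      class = c("hydrophobic", "hydrophobic", "hydrophobic",
                "hydrophilic", "hydrophilic", "hydrophilic",
                "hydrophobic", "charged"),
      charge = c(0, 0, 0, 0, 0, 0, 0, -1)
    ),
    `NA` = tibble::tibble(bead = "NA", class = "charged", charge = 1),
    W = tibble::tibble(bead = "W", class = "hydrophilic", charge = 0)
  )
}

#' Net charge of a molecule kind
#' @param kind Molecule kind, as in [bead_topology()].
#' @return Net charge in elementary units.
#' @export
molecule_charge <- function(kind) sum(bead_topology(kind)$charge)

#' Construct a coarse-grained frame
#'
#' A frame is a snapshot of the cubic simulation cell: a beads table plus
#' the box edge and the time stamp. Coordinates are wrapped into
#' `[0, box)` on construction; periodic geometry is handled by the
#' minimum-image helpers.
#'
#' @param beads A data frame with columns `molecule_id` (integer, grouping
#'   beads into molecules), `kind` (molecule kind), `bead` (bead name) and
#'   coordinates `x`, `y`, `z` in Angstrom.
#' @param box Cubic box edge length (Angstrom), positive.
#' @param time Frame time in microseconds.
#' @param validate Check bead counts and names against [bead_topology()].
#' @return An object of class `cg_frame`: a list with elements `beads`
#'   (tibble, with `class` and `charge` columns filled in), `box`, `time`.
#' @export
cg_frame <- function(beads, box, time = 0, validate = TRUE) {
  required <- c("molecule_id", "kind", "bead", "x", "y", "z")
  missing <- setdiff(required, names(beads))
  if (length(missing)) {
    abort(paste0("`beads` is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  if (!is.finite(box) || box <= 0) abort("`box` must be a positive length.")
  if (any(!is.finite(beads$x)) || any(!is.finite(beads$y)) ||
      any(!is.finite(beads$z))) {
    abort("All bead coordinates must be finite.")
  }
  beads <- tibble::as_tibble(beads)
  beads$x <- beads$x %% box
  beads$y <- beads$y %% box
  beads$z <- beads$z %% box
  if (validate) {
    chk <- dplyr::summarise(dplyr::group_by(beads, .data$molecule_id,
                                            .data$kind),
                            n = dplyr::n(), .groups = "drop")
    expected <- vapply(chk$kind, function(k) nrow(bead_topology(k)),
                       integer(1))
    bad <- chk$n != expected
    if (any(bad)) {
      abort(paste0("Bead count does not match topology for molecule(s): ",
                   paste(chk$molecule_id[bad], collapse = ", ")))
    }
  }
  # annotate class/charge from the topology
  topo <- dplyr::bind_rows(lapply(unique(beads$kind), function(k) {
    dplyr::mutate(bead_topology(k), kind = k)
  }))
  beads <- dplyr::left_join(beads, topo, by = c("kind", "bead"))
  if (any(is.na(beads$charge))) {
    abort("Unknown bead name(s) for their molecule kind.")
  }
  structure(list(beads = beads, box = box, time = time), class = "cg_frame")
}

#' @export
print.cg_frame <- function(x, ...) {
  comp <- table(dplyr::distinct(x$beads, .data$molecule_id, .data$kind)$kind)
  cat(sprintf("<cg_frame> t = %g us, box = %g A, %d beads, molecules: %s\n",
              x$time, x$box, nrow(x$beads),
              paste(names(comp), comp, sep = ":", collapse = " ")))
  invisible(x)
}

frame_composition <- function(frame) {
  mol <- dplyr::distinct(frame$beads, .data$molecule_id, .data$kind)
  table(factor(mol$kind, levels = c("SDS", "CA", "NA", "W")))
}

#' Construct a coarse-grained trajectory
#'
#' @param frames A list of [cg_frame()] objects with strictly increasing
#'   times and identical molecular composition (no molecules created or
#'   destroyed).
#' @return An object of class `cg_trajectory`: list with `frames` and
#'   `composition` (named counts of molecule kinds).
#' @export
cg_trajectory <- function(frames) {
  if (!length(frames)) abort("A trajectory needs at least one frame.")
  if (!all(vapply(frames, inherits, logical(1), "cg_frame"))) {
    abort("All elements of `frames` must be cg_frame objects.")
  }
  times <- vapply(frames, function(f) f$time, numeric(1))
  if (length(times) > 1L && any(diff(times) <= 0)) {
    abort("Frame times must be strictly increasing.")
  }
  comps <- lapply(frames, frame_composition)
  if (length(comps) > 1L &&
      !all(vapply(comps[-1], identical, logical(1), comps[[1]]))) {
    abort("Molecular composition must be constant across frames.")
  }
  structure(list(frames = frames, composition = comps[[1]]),
            class = "cg_trajectory")
}

#' @export
print.cg_trajectory <- function(x, ...) {
  times <- trajectory_times(x)
  cat(sprintf("<cg_trajectory> %d frames, t = %g..%g us, molecules: %s\n",
              length(x$frames), min(times), max(times),
              paste(names(x$composition), x$composition, sep = ":",
                    collapse = " ")))
  invisible(x)
}

#' Frame times of a trajectory (microseconds)
#' @param traj A `cg_trajectory`.
#' @return Numeric vector of frame times.
#' @export
trajectory_times <- function(traj) {
  vapply(traj$frames, function(f) f$time, numeric(1))
}

#' Minimum-image distance between two points in a cubic periodic box
#'
#' @param p,q Numeric length-3 coordinates, or matrices with 3 columns
#'   (paired row-wise), in Angstrom.
#' @param box Cubic box edge (Angstrom).
#' @return Euclidean distance(s) under the cubic minimum-image convention;
#'   always in `[0, box * sqrt(3) / 2]`.
#' @export
minimum_image_distance <- function(p, q, box) {
  if (!is.finite(box) || box <= 0) abort("`box` must be positive.")
  p <- rbind(p); q <- rbind(q)
  d <- p - q
  d <- d - box * round(d / box)
  unname(sqrt(rowSums(d^2)))
}

min_image_disp <- function(d, box) d - box * round(d / box)

#' Closest-bead distance between two molecules under periodic boundaries
#'
#' The cluster criterion of the analysis: the minimum over all bead pairs of
#' the minimum-image distance.
#'
#' @param mol_a,mol_b Matrices of bead coordinates (rows = beads, columns =
#'   x, y, z) in Angstrom.
#' @param box Cubic box edge (Angstrom).
#' @return The smallest bead-bead minimum-image distance (Angstrom).
#' @export
closest_bead_distance <- function(mol_a, mol_b, box) {
  mol_a <- rbind(mol_a); mol_b <- rbind(mol_b)
  if (!nrow(mol_a) || !nrow(mol_b)) abort("Both molecules must be non-empty.")
  idx <- expand.grid(i = seq_len(nrow(mol_a)), j = seq_len(nrow(mol_b)))
  min(minimum_image_distance(mol_a[idx$i, , drop = FALSE],
                             mol_b[idx$j, , drop = FALSE], box))
}

#' Effective molar concentration of n molecules in a box
#'
#' Converts a molecule count and a box volume to a molar concentration:
#' `c = n / (N_A * V)`. Sixty surfactants in an 8114.11 nm^3 cell give
#' 12.28 mM.
#'
#' @param n_molecules Number of molecules (non-negative).
#' @param volume_nm3 Box volume in nm^3, positive.
#' @return Concentration in mM.
#' @examples
#' effective_concentration(60, 8114.11) # 12.28 mM
#' @export
effective_concentration <- function(n_molecules, volume_nm3) {
  if (any(n_molecules < 0)) abort("`n_molecules` must be non-negative.")
  if (any(!is.finite(volume_nm3)) || any(volume_nm3 <= 0)) {
    abort("`volume_nm3` must be positive.")
  }
  avogadro <- 6.02214076e23
  litres <- volume_nm3 * 1e-24
  n_molecules / (avogadro * litres) * 1e3
}

#' Box edge (Angstrom) giving a target surfactant concentration
#'
#' Inverse of [effective_concentration()] for a cubic cell.
#'
#' @param n_molecules Number of surfactant molecules.
#' @param conc_mM Target concentration in mM.
#' @return Cubic box edge length in Angstrom.
#' @export
box_for_concentration <- function(n_molecules, conc_mM) {
  avogadro <- 6.02214076e23
  vol_L <- n_molecules / (avogadro * conc_mM / 1e3)
  (vol_L * 1e24)^(1 / 3) * 10 # L -> nm^3 -> nm -> A
}

# ---- molecule-level geometry helpers ----

#' Per-molecule bead coordinate list of a frame
#'
#' @param frame A `cg_frame`.
#' @param kinds Molecule kinds to keep (default: the surfactants).
#' @return A list with `coords` (list of per-molecule coordinate matrices),
#'   `molecule_id` and `kind` vectors, in order of first appearance.
#' @export
frame_molecules <- function(frame, kinds = c("SDS", "CA")) {
  b <- frame$beads[frame$beads$kind %in% kinds, , drop = FALSE]
  ids <- unique(b$molecule_id)
  coords <- lapply(ids, function(id) {
    m <- b[b$molecule_id == id, c("x", "y", "z")]
    as.matrix(m)
  })
  kind <- vapply(ids, function(id) b$kind[b$molecule_id == id][1],
                 character(1))
  list(coords = coords, molecule_id = ids, kind = kind)
}

#' Closest-bead distance matrix between molecules of a frame
#'
#' @inheritParams frame_molecules
#' @return A symmetric matrix of closest-bead minimum-image distances
#'   (Angstrom) between all pairs of selected molecules.
#' @export
closest_bead_matrix <- function(frame, kinds = c("SDS", "CA")) {
  mols <- frame_molecules(frame, kinds)
  n <- length(mols$coords)
  if (!n) abort("Frame contains no molecules of the requested kinds.")
  pos <- do.call(rbind, mols$coords)
  mol_index <- rep.int(seq_len(n) - 1L, vapply(mols$coords, nrow, integer(1)))
  m <- cpp_closest_bead_matrix(pos, mol_index, n, frame$box)
  dimnames(m) <- list(mols$molecule_id, mols$molecule_id)
  m
}

#' Unwrap a set of coordinates across periodic boundaries
#'
#' Reconstructs a contiguous cluster from wrapped coordinates by applying
#' the minimum-image displacement of every bead relative to a reference
#' point. Valid for clusters smaller than half the box in every direction.
#'
#' @param coords Matrix of bead coordinates (rows = beads).
#' @param box Cubic box edge (Angstrom).
#' @param ref Reference coordinate (default: the first bead).
#' @return Matrix of unwrapped coordinates.
#' @export
unwrap_coords <- function(coords, box, ref = coords[1, ]) {
  coords <- rbind(coords)
  d <- sweep(coords, 2, ref)
  sweep(min_image_disp(d, box), 2, ref, `+`)
}
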