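#' Specification of a toy stochastic aggregation run
#'
#' A desk-scale implicit-solvent stand-in for a long coarse-grained
#' self-assembly simulation: overdamped Langevin dynamics on bead chains
#' with harmonic bonds, Lennard-Jones attraction among hydrophobic beads
#' (strongest between SDS tail beads, weaker for cholate ring beads and for
#' the cross pair) and a screened-Coulomb term between charged beads and
#' counterions. It makes no claim of force-field fidelity; its purpose is a
#' trajectory whose qualitative mechanism (spontaneous aggregation, an
#' SDS-rich core, loosely bound cholate, a small condensed-ion population)
#' exercises every analysis stage.
#'
#' @param n_sds,n_ca Numbers of surfactant molecules (default 30 + 30, the
#'   composition of the reference system).
#' @param box Cubic box edge in Angstrom. Default: the edge that gives the
#'   reference effective surfactant concentration of 12.28 mM for
#'   `n_sds + n_ca` molecules (about 201 Angstrom for 60).
#' @param attraction Hydrophobic well-depth scale (reduced energy units,
#'   kT = 1). 0 switches the hydrophobic attraction off entirely.
#' @param repulsion_range Screening length of the charged-bead interaction
#'   (Angstrom).
#' @param coul_strength Prefactor of the screened-Coulomb term.
#' @param step_size Reduced time step of the overdamped integrator.
#' @param n_steps Number of integration steps.
#' @param stride Steps between saved frames.
#' @param temperature Reduced temperature (friction coefficient is 1).
#' @param time_total_us Nominal trajectory span in microseconds assigned to
#'   the saved frames (linear mapping), so that the windowed analyses can
#'   use their physical defaults.
#' @param seed Integer seed.
#' @return A list of class `toy_sim_spec`.
#' @export
toy_sim_spec <- function(n_sds = 30, n_ca = 30, box = NULL,
                         attraction = 4.5, repulsion_range = 10,
                         coul_strength = 15, step_size = 0.02,
                         n_steps = 40000, stride = 400, temperature = 1,
                         time_total_us = 10, seed = 1L) {
  if (n_steps < 1) abort("`n_steps` must be positive.")
  if (step_size <= 0 || !is.finite(step_size)) {
    abort("`step_size` must be positive and finite.")
  }
  if (is.null(box)) {
    box <- box_for_concentration(n_sds + n_ca, 12.28)
  }
  structure(list(n_sds = as.integer(n_sds), n_ca = as.integer(n_ca),
                 box = box, attraction = attraction,
                 repulsion_range = repulsion_range,
                 coul_strength = coul_strength, step_size = step_size,
                 n_steps = as.integer(n_steps), stride = as.integer(stride),
                 temperature = temperature,
                 time_total_us = time_total_us, seed = as.integer(seed)),
            class = "toy_sim_spec")
}

# bead interaction classes of the toy model
toy_bead_type <- function(kind, bead) {
  ifelse(kind == "SDS" & bead %in% c("C4", "C2", "C1"), 0L,
  ifelse(kind == "CA" & bead %in% c("R1", "R2", "R3", "C1"), 1L,
  ifelse(kind == "CA" & bead %in% c("RO2", "RO3", "ROH"), 2L,
  ifelse(bead %in% c("SO3", "OCO"), 3L, 4L))))
}

toy_eps_matrix <- function(attraction) {
  base <- 0.3 # shallow well: excluded volume, effectively non-sticky at kT=1
  eps <- matrix(base, 5, 5)
  eps[1, 1] <- base + attraction            # SDS tail - SDS tail
  eps[1, 2] <- eps[2, 1] <- base + 0.30 * attraction # SDS tail - CA ring
  eps[2, 2] <- base + 0.05 * attraction     # CA ring - CA ring
  eps
}

#' Run the toy stochastic aggregation simulator
#'
#' Initialises all molecules at random positions and orientations in the
#' periodic box (so every surfactant starts as its own cluster), then
#' integrates overdamped Langevin dynamics and returns the saved frames as
#' a trajectory. Deterministic given the spec's seed. The integrator aborts
#' with a diagnostic if a coordinate becomes non-finite (step-size
#' instability).
#'
#' @param spec A [toy_sim_spec()].
#' @return A [cg_trajectory()] whose frame times span
#'   `[0, spec$time_total_us]`.
#' @export
run_toy_aggregation <- function(spec) {
  if (!inherits(spec, "toy_sim_spec")) abort("`spec` must be a toy_sim_spec.")
  with_preserved_seed(spec$seed, run_toy_aggregation_impl(spec))
}

run_toy_aggregation_impl <- function(spec) {
  b0 <- 4.0
  kinds <- c(rep("SDS", spec$n_sds), rep("CA", spec$n_ca),
             rep("NA", spec$n_sds + spec$n_ca))
  beads <- list()
  bonds <- list()
  offset <- 0L
  for (mi in seq_along(kinds)) {
    topo <- bead_topology(kinds[mi])
    nb <- nrow(topo)
    centre <- runif(3, 0, spec$box)
    dir <- rnorm(3); dir <- dir / sqrt(sum(dir^2))
    pos <- centre + outer(seq_len(nb) - (nb + 1) / 2, dir) * b0
    beads[[mi]] <- tibble::tibble(
      molecule_id = mi, kind = kinds[mi], bead = topo$bead,
      x = pos[, 1], y = pos[, 2], z = pos[, 3],
      type = toy_bead_type(kinds[mi], topo$bead), charge = topo$charge
    )
    if (nb > 1L) {
      bonds[[length(bonds) + 1L]] <-
        cbind(offset + seq_len(nb - 1L) - 1L, offset + seq_len(nb - 1L))
    }
    offset <- offset + nb
  }
  btab <- dplyr::bind_rows(beads)
  bond_mat <- if (length(bonds)) do.call(rbind, bonds) else
    matrix(integer(0), ncol = 2)
  pos0 <- as.matrix(btab[, c("x", "y", "z")]) %% spec$box
  snaps <- cpp_toy_langevin(
    pos0, btab$type, bond_mat, btab$charge,
    toy_eps_matrix(spec$attraction), 4.3, 12.0, 10.0, b0,
    spec$coul_strength, spec$repulsion_range, spec$box,
    spec$step_size, spec$temperature, spec$n_steps, spec$stride, 60.0
  )
  times <- seq(0, spec$time_total_us, length.out = length(snaps))
  frames <- lapply(seq_along(snaps), function(i) {
    s <- snaps[[i]]
    cg_frame(tibble::tibble(
      molecule_id = btab$molecule_id, kind = btab$kind, bead = btab$bead,
      x = s[, 1], y = s[, 2], z = s[, 3]
    ), box = spec$box, time = times[i], validate = FALSE)
  })
  cg_trajectory(frames)
}
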