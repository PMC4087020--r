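# Gyration-tensor shape descriptors, radial structure, orientation angles.

test_that("K^2 hits its landmark values", {
  # collinear beads: K^2 = 1
  expect_equal(gyration_anisotropy(cbind(seq(0, 9), 0, 0))$k2, 1)
  # regular tetrahedron: spherically symmetric class, K^2 = 0
  tet <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))
  expect_equal(gyration_anisotropy(tet)$k2, 0, tolerance = 1e-12)
  # principal moments (2, 1, 0): K^2 = 1 - 3 * 2 / 9 = 1/3
  pts <- rbind(c(2, 0, 0), c(-2, 0, 0), c(0, sqrt(2), 0), c(0, -sqrt(2), 0))
  g <- gyration_anisotropy(pts)
  expect_equal(g$lambda, c(2, 1, 0), tolerance = 1e-12)
  expect_equal(g$k2, 1 / 3, tolerance = 1e-12)
  # degenerate point: all beads coincident
  expect_equal(gyration_anisotropy(matrix(5, 4, 3))$k2, 0)
  expect_error(gyration_anisotropy(matrix(1, 1, 3)), "at least 2")
})

test_that("K^2 is invariant under rotation, translation and scaling", {
  set.seed(91)
  for (i in 1:10) {
    co <- matrix(rnorm(3 * 25), ncol = 3)
    k0 <- gyration_anisotropy(co)$k2
    rot <- qr.Q(qr(matrix(rnorm(9), 3)))
    co2 <- co %*% rot
    co2 <- sweep(co2, 2, runif(3, -50, 50), `+`) * 3.7
    expect_equal(gyration_anisotropy(co2)$k2, k0, tolerance = 1e-9)
  }
})

test_that("K^2 stays within [0, 1] on randomised bead sets", {
  set.seed(101)
  for (i in 1:200) {
    n <- sample(2:40, 1)
    co <- matrix(rnorm(3 * n, sd = runif(1, 0.1, 20)), ncol = 3)
    k2 <- gyration_anisotropy(co)$k2
    expect_gte(k2, 0)
    expect_lte(k2, 1)
  }
})

test_that("spherical micelles are nearly isotropic, rods are not", {
  # beads uniform in a ball: K^2 well below 0.1
  sph <- config_spec(clusters = list(list(n_sds = 25, n_ca = 15,
                                          geometry = "sphere")),
                     box = 240, seed = 23)
  traj <- static_trajectory(build_configuration(sph)$frame, c(0, 0.1))
  sb <- shape_by_size(traj, window_us = c(0, 0.1))
  expect_lt(sb$mean_k2[sb$size == 40], 0.1)
  # rod-like aggregate: strongly anisotropic
  rod <- config_spec(clusters = list(list(n_sds = 10, n_ca = 10,
                                          geometry = "rod", radius = 3)),
                     box = 240, seed = 25)
  traj2 <- static_trajectory(build_configuration(rod)$frame, c(0, 0.1))
  sb2 <- shape_by_size(traj2, window_us = c(0, 0.1))
  expect_gt(sb2$mean_k2[sb2$size == 20], 0.4)
  # near-collinear dimers are highly anisotropic
  dimer <- frame_of(mol_cloud("SDS", c(50, 50, 50), 1, spread = 0.3),
                    mol_cloud("SDS", c(56, 50, 50), 2, spread = 0.3),
                    box = 200)
  set.seed(27)
  sb3 <- shape_by_size(static_trajectory(dimer, c(0, 0.1)),
                       window_us = c(0, 0.1))
  expect_gt(sb3$mean_k2[sb3$size == 2], 0.4)
})

# a micelle of n SDS whose tail beads sit at the centre and whose SO3 heads
# sit on antipodal pairs of a sphere of radius r: the COM is exactly the
# centre and every SO3 is exactly r from it
shell_micelle <- function(n_pairs = 10, r = 16, centre = c(100, 100, 100),
                          inward = TRUE) {
  dirs <- matrix(rnorm(3 * n_pairs), ncol = 3)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  dirs <- rbind(dirs, -dirs)
  mols <- lapply(seq_len(nrow(dirs)), function(i) {
    u <- dirs[i, ]
    sgn <- if (inward) -1 else 1
    tibble::tibble(molecule_id = i, kind = "SDS",
                   bead = c("C4", "C2", "C1", "SO3"),
                   x = centre[1] + c((r + sgn * 9) * u[1], (r + sgn * 6) * u[1],
                                     (r + sgn * 3) * u[1], r * u[1]),
                   y = centre[2] + c((r + sgn * 9) * u[2], (r + sgn * 6) * u[2],
                                     (r + sgn * 3) * u[2], r * u[2]),
                   z = centre[3] + c((r + sgn * 9) * u[3], (r + sgn * 6) * u[3],
                                     (r + sgn * 3) * u[3], r * u[3]))
  })
  cg_frame(dplyr::bind_rows(mols), box = 200)
}

test_that("radial profiles localise shells and normalise per selector", {
  set.seed(111)
  fr <- shell_micelle(n_pairs = 10, r = 16)
  traj <- static_trajectory(fr, c(0, 0.1))
  prof <- radial_profile(traj, "SDS", "SO3", cutoff = 40,
                         window_us = c(0, 0.1), min_size = 20)
  expect_equal(sum(prof$density), 1)
  # heads exactly at 16 A: all mass in the [16, 17) bin
  expect_equal(prof$density[prof$r == 16.5], 1)
  # the innermost tail bead C4 (r + sgn*9 = 7) peaks inside the head shell
  prof_c4 <- radial_profile(traj, "SDS", "C4", cutoff = 40,
                            window_us = c(0, 0.1), min_size = 20)
  expect_equal(sum(prof_c4$density), 1)
  expect_equal(prof_c4$density[prof_c4$r == 7.5], 1)
  expect_lt(which.max(prof_c4$density), which.max(prof$density))
  expect_error(radial_profile(traj, "SDS", "XX", window_us = c(0, 0.1)),
               "does not exist")
  expect_error(radial_profile(traj, "CA", "OCO", cutoff = 40,
                              window_us = c(0, 0.1), min_size = 20),
               "matched no beads")
})

test_that("orientation angles read 0 inward, 180 outward, ~90 when random", {
  set.seed(121)
  inward <- static_trajectory(shell_micelle(inward = TRUE), c(0, 0.1))
  ang_in <- orientation_angles(inward, cutoff = 40, window_us = c(0, 0.1),
                               min_size = 20)
  expect_equal(sum(ang_in$frequency), 1)
  # tails pointing at the COM: every angle in the first bin
  expect_equal(sum(ang_in$frequency[ang_in$theta < 10]), 1)
  outward <- static_trajectory(shell_micelle(inward = FALSE), c(0, 0.1))
  ang_out <- orientation_angles(outward, cutoff = 40, window_us = c(0, 0.1),
                                min_size = 20)
  expect_equal(sum(ang_out$frequency[ang_out$theta > 170]), 1)
  # isotropic tails: mean angle near 90 degrees with sin-weighted density
  rand_frame <- local({
    dirs <- matrix(rnorm(3 * 150), ncol = 3)
    dirs <- dirs / sqrt(rowSums(dirs^2))
    pos <- matrix(rnorm(3 * 150, sd = 8), ncol = 3) + 100
    mols <- lapply(1:150, function(i) {
      u <- dirs[i, ]
      p <- pos[i, ]
      tibble::tibble(molecule_id = i, kind = "SDS",
                     bead = c("C4", "C2", "C1", "SO3"),
                     x = p[1] + c(9, 6, 3, 0) * u[1],
                     y = p[2] + c(9, 6, 3, 0) * u[2],
                     z = p[3] + c(9, 6, 3, 0) * u[3])
    })
    cg_frame(dplyr::bind_rows(mols), box = 400)
  })
  ang <- orientation_angles(static_trajectory(rand_frame, c(0, 0.1)),
                            cutoff = 40, window_us = c(0, 0.1),
                            min_size = 20)
  mean_theta <- sum(ang$theta * ang$frequency)
  expect_gt(mean_theta, 80)
  expect_lt(mean_theta, 100)
})

test_that("orientation histograms are invariant under global rotation", {
  set.seed(131)
  fr <- shell_micelle(n_pairs = 12, r = 14)
  rot <- qr.Q(qr(matrix(rnorm(9), 3)))
  b <- fr$beads
  co <- as.matrix(b[, c("x", "y", "z")]) - 100
  co2 <- co %*% rot + 100
  fr2 <- cg_frame(dplyr::mutate(b[, c("molecule_id", "kind", "bead")],
                                x = co2[, 1], y = co2[, 2], z = co2[, 3]),
                  box = 200)
  a1 <- orientation_angles(static_trajectory(fr, c(0, 0.1)), cutoff = 40,
                           window_us = c(0, 0.1), min_size = 20)
  a2 <- orientation_angles(static_trajectory(fr2, c(0, 0.1)), cutoff = 40,
                           window_us = c(0, 0.1), min_size = 20)
  expect_equal(a1$frequency, a2$frequency, tolerance = 1e-12)
})
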