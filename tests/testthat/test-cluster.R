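# Micelle identification and aggregation statistics.

test_that("constructed geometries cluster exactly as built", {
  # A-B gap 5 A (joined), B-C gap 30 A (separate)
  fr <- frame_of(mol_cloud("SDS", c(10, 10, 10), 1),
                 mol_cloud("SDS", c(15, 10, 10), 2),
                 mol_cloud("CA", c(45, 10, 10), 3),
                 box = 200)
  a <- find_clusters(fr)
  expect_equal(a$n_clusters, 2)
  expect_equal(a$labels$cluster, c(1, 1, 2))
  expect_equal(sort(a$clusters$size), c(1, 2))
  # strict inequality at the cutoff: exactly 7 A is not joined
  fr7 <- frame_of(mol_cloud("SDS", c(10, 10, 10), 1),
                  mol_cloud("SDS", c(17, 10, 10), 2), box = 200)
  expect_equal(find_clusters(fr7, cutoff = 7)$n_clusters, 2)
  fr69 <- frame_of(mol_cloud("SDS", c(10, 10, 10), 1),
                   mol_cloud("SDS", c(16.9, 10, 10), 2), box = 200)
  expect_equal(find_clusters(fr69, cutoff = 7)$n_clusters, 1)
  expect_error(find_clusters(fr, cutoff = 0), "positive")
})

test_that("well-separated molecules are all singletons", {
  # 60 molecules on a 20 A grid in a large box: every gap far exceeds 7 A
  centres <- as.matrix(expand.grid(x = seq(10, 70, 20), y = seq(10, 70, 20),
                                   z = seq(10, 70, 20)))[1:60, ]
  mols <- lapply(1:60, function(i) {
    mol_cloud(if (i %% 2) "SDS" else "CA", centres[i, ], i)
  })
  fr <- cg_frame(dplyr::bind_rows(mols), box = 300)
  expect_equal(find_clusters(fr)$n_clusters, 60)
})

test_that("components match a brute-force union-find oracle on random frames", {
  set.seed(61)
  for (rep in 1:25) {
    n <- sample(5:20, 1)
    box <- 55
    mols <- lapply(seq_len(n), function(i) {
      mol_cloud(sample(c("SDS", "CA"), 1), runif(3, 0, box), i, spread = 1.5)
    })
    fr <- cg_frame(dplyr::bind_rows(mols), box = box)
    got <- find_clusters(fr, cutoff = 7)$labels$cluster
    want <- bf_components(frame_molecules(fr)$coords, box, 7)
    expect_identical(partition_canon(got), partition_canon(want))
  }
})

test_that("cluster labels are invariant under translation and reordering", {
  set.seed(71)
  mols <- lapply(1:12, function(i) {
    mol_cloud(sample(c("SDS", "CA"), 1), runif(3, 0, 60), i, spread = 1)
  })
  fr <- cg_frame(dplyr::bind_rows(mols), box = 60)
  base <- find_clusters(fr)
  # translation by an arbitrary vector (wrapped)
  shifted <- dplyr::bind_rows(mols)
  shifted$x <- shifted$x + 23.7; shifted$y <- shifted$y - 41.2
  a2 <- find_clusters(cg_frame(shifted, box = 60))
  expect_identical(partition_canon(base$labels$cluster),
                   partition_canon(a2$labels$cluster))
  # molecule reordering: same partition as a set of sets
  perm <- sample(12)
  reord <- dplyr::bind_rows(mols[perm])
  a3 <- find_clusters(cg_frame(reord, box = 60))
  grp_base <- split(base$labels$molecule_id, base$labels$cluster)
  grp_perm <- split(a3$labels$molecule_id, a3$labels$cluster)
  canon <- function(g) unname(lapply(g, sort))[order(vapply(lapply(g, sort), `[`, numeric(1), 1))]
  expect_identical(canon(grp_base), canon(grp_perm))
})

test_that("cutoff limits give all singletons or one cluster, sizes conserve", {
  set.seed(81)
  mols <- lapply(1:15, function(i) {
    mol_cloud(sample(c("SDS", "CA"), 1), runif(3, 0, 50), i, spread = 1)
  })
  fr <- cg_frame(dplyr::bind_rows(mols), box = 50)
  expect_equal(find_clusters(fr, cutoff = 1e-6)$n_clusters, 15)
  expect_equal(find_clusters(fr, cutoff = 2 * 50 * sqrt(3))$n_clusters, 1)
  for (cut in c(3, 7, 15)) {
    a <- find_clusters(fr, cutoff = cut)
    expect_equal(sum(a$clusters$size), 15)
  }
})

test_that("block averaging tiles the window and handles degenerate input", {
  t <- seq(0, 1, by = 0.01)
  bs <- block_series(t, rep(4, length(t)), block_ns = 100,
                     window_us = c(0, 1))
  expect_true(all(bs$blocks$block_mean == 4))
  expect_equal(bs$mean, 4)
  expect_equal(bs$sd, 0)
  expect_equal(nrow(bs$blocks), 10)
  # trailing partial block is dropped with a warning
  expect_warning(block_series(seq(0, 0.95, by = 0.01), rnorm(96),
                              block_ns = 300, window_us = c(0, 0.95)),
                 "partial block")
  expect_error(block_series(t, rep(1, length(t)), block_ns = 100,
                            window_us = c(0, 0.05)),
               "shorter than one block")
  expect_error(noc_series(static_trajectory(
    frame_of(mol_cloud("SDS", c(5, 5, 5), 1)), c(0, 0.1)),
    window_us = c(5, 6)), "window")
})

test_that("the NOC series of a static trajectory is flat", {
  fr <- frame_of(mol_cloud("SDS", c(10, 10, 10), 1),
                 mol_cloud("SDS", c(14, 10, 10), 2),
                 mol_cloud("CA", c(60, 60, 60), 3), box = 200)
  traj <- static_trajectory(fr, seq(0, 1, by = 0.05))
  ns <- noc_series(traj, block_ns = 100, window_us = c(0, 1))
  expect_equal(ns$mean, 2)
  expect_equal(ns$sd, 0)
  expect_true(all(ns$blocks$block_mean == 2))
})

test_that("size distributions are normalised with peaks at the planted sizes", {
  cfg <- config_spec(clusters = list(list(n_sds = 8, n_ca = 4,
                                          geometry = "sphere")),
                     free_sds = 1, free_ca = 1, box = 200, seed = 3)
  fr <- build_configuration(cfg)$frame
  traj <- static_trajectory(fr, c(0, 0.1))
  d <- size_distribution(traj, window_us = c(0, 0.1))
  expect_equal(sum(d$frequency), 1)
  expect_equal(d$frequency[d$size == 1], 2 / 3)
  expect_equal(d$frequency[d$size == 12], 1 / 3)
  # the trimodal layout: planted sizes 1, 12 and 41 are exactly the modes
  cfg2 <- config_spec(clusters = list(list(n_sds = 8, n_ca = 4,
                                           geometry = "sphere"),
                                      list(n_sds = 28, n_ca = 13,
                                           geometry = "sphere")),
                      free_sds = 1, free_ca = 6, box = 260, seed = 5)
  fr2 <- build_configuration(cfg2)$frame
  d2 <- size_distribution(static_trajectory(fr2, c(0, 0.1)),
                          window_us = c(0, 0.1))
  expect_setequal(d2$size, c(1, 12, 41))
  expect_equal(sum(d2$frequency), 1)
})

test_that("SDS content by size does the arithmetic and weights clusters equally", {
  cfg <- config_spec(clusters = list(list(n_sds = 28, n_ca = 13,
                                          geometry = "sphere"),
                                     list(n_sds = 10, n_ca = 0,
                                          geometry = "sphere"),
                                     list(n_sds = 0, n_ca = 8,
                                          geometry = "sphere")),
                     box = 300, seed = 11)
  fr <- build_configuration(cfg)$frame
  traj <- static_trajectory(fr, 0) # one frame: each size observed once
  x2 <- sds_content_by_size(traj, window_us = c(0, 0.1))
  expect_equal(x2$mean_x2[x2$size == 41], 28 / 41)
  expect_equal(x2$mean_x2[x2$size == 10], 1)
  expect_equal(x2$mean_x2[x2$size == 8], 0)
  # equal weight per cluster, not per molecule
  expect_equal(attr(x2, "global_mean"), mean(c(28 / 41, 1, 0)))
  # a size observed once has no spread estimate
  expect_true(all(is.na(x2$sd_x2)))
})

test_that("free-monomer statistics mirror the constructed partition", {
  cfg <- config_spec(clusters = list(list(n_sds = 28, n_ca = 13,
                                          geometry = "sphere")),
                     free_sds = 0, free_ca = 17, n_na = 60, box = 260,
                     seed = 13)
  fr <- build_configuration(cfg)$frame
  traj <- static_trajectory(fr, c(0, 0.1))
  fm <- free_monomer_stats(traj, window_us = c(0, 0.1))
  expect_equal(fm$frac_free, 17 / 58)
  expect_equal(fm$frac_free_ca, 1)
  expect_equal(fm$frac_free_sds, 0)
  # everyone aggregated
  one <- config_spec(clusters = list(list(n_sds = 5, n_ca = 5,
                                          geometry = "sphere")),
                     box = 200, seed = 15)
  fm2 <- free_monomer_stats(static_trajectory(
    build_configuration(one)$frame, c(0, 0.1)), window_us = c(0, 0.1))
  expect_equal(fm2$frac_free, 0)
  # everyone free
  all_free <- config_spec(free_sds = 3, free_ca = 3, box = 200, seed = 17)
  fm3 <- free_monomer_stats(static_trajectory(
    build_configuration(all_free)$frame, c(0, 0.1)), window_us = c(0, 0.1))
  expect_equal(fm3$frac_free, 1)
})
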