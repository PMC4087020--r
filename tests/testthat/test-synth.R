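# Ground-truthed generators: curves, configurations, toy dynamics.

test_that("generators are bit-identical under identical specs and seeds", {
  sp <- curve_spec("titration",
                   list(a1 = 1.8, a2 = 1.2, x0 = 4.07, dx = 0.3),
                   noise_sd = 0.02, seed = 7)
  expect_identical(generate_curve(sp), generate_curve(sp))
  cfg <- config_spec(clusters = list(list(n_sds = 6, n_ca = 6,
                                          geometry = "sphere")),
                     free_ca = 2, planted_condensed = 3, box = 200,
                     seed = 19)
  expect_identical(build_configuration(cfg)$frame$beads,
                   build_configuration(cfg)$frame$beads)
  ts <- toy_sim_spec(n_sds = 4, n_ca = 4, n_steps = 300, stride = 100,
                     seed = 5)
  t1 <- run_toy_aggregation(ts)
  t2 <- run_toy_aggregation(ts)
  expect_identical(t1$frames[[length(t1$frames)]]$beads,
                   t2$frames[[length(t2$frames)]]$beads)
  # generators leave the caller's RNG stream untouched
  set.seed(99); before <- runif(5)
  set.seed(99); invisible(generate_curve(sp)); after <- runif(5)
  expect_identical(before, after)
})

test_that("noiseless curves lie exactly on their generating model", {
  sp <- curve_spec("titration",
                   list(a1 = 1.8, a2 = 1.2, x0 = 4.07, dx = 0.3),
                   noise_sd = 0, n_points = 12, seed = 1)
  cur <- generate_curve(sp)
  expect_equal(cur$y,
               1.2 + (1.8 - 1.2) / (1 + exp((cur$x - 4.07) / 0.3)))
  # truth is carried along for recovery tests
  expect_equal(attr(cur, "truth")$x0, 4.07)
})

test_that("planted configurations round-trip through cluster and ion analyses", {
  set.seed(161)
  for (rep in 1:25) {
    n_cl <- sample(0:2, 1)
    clusters <- lapply(seq_len(n_cl), function(i) {
      list(n_sds = sample(2:12, 1), n_ca = sample(0:10, 1),
           geometry = sample(c("sphere", "rod"), 1))
    })
    free_sds <- sample(0:4, 1)
    free_ca <- sample(0:6, 1)
    n_surf <- sum(vapply(clusters, function(cl) cl$n_sds + cl$n_ca,
                         numeric(1))) + free_sds + free_ca
    if (n_surf == 0) next
    planted <- sample(0:min(6, n_surf), 1)
    cfg <- config_spec(clusters = clusters, free_sds = free_sds,
                       free_ca = free_ca, planted_condensed = planted,
                       box = 320, seed = rep)
    bc <- build_configuration(cfg)
    a <- find_clusters(bc$frame)
    expect_equal(a$n_clusters, bc$truth$n_clusters)
    expect_identical(partition_canon(a$labels$cluster),
                     partition_canon(bc$truth$labels$cluster))
    expect_equal(sort(a$clusters$size), sort(bc$truth$sizes))
    p <- classify_ions(bc$frame)
    expect_equal(p$n_condensed, bc$truth$n_condensed)
    expect_equal(p$n_total, bc$truth$n_na)
  }
})

test_that("the planted 41-molecule micelle with free cholate mirrors the reference layout", {
  cfg <- config_spec(clusters = list(list(n_sds = 28, n_ca = 13,
                                          geometry = "sphere")),
                     free_sds = 2, free_ca = 17, planted_condensed = 6,
                     box = 260, seed = 7)
  bc <- build_configuration(cfg)
  a <- find_clusters(bc$frame)
  expect_equal(a$n_clusters, 20) # 1 micelle + 19 singletons
  expect_equal(max(a$clusters$size), 41)
  expect_equal(a$clusters$sds_fraction[a$clusters$size == 41], 28 / 41)
  expect_equal(classify_ions(bc$frame)$n_condensed, 6)
})

test_that("configuration specs validate their geometry and feasibility", {
  expect_error(config_spec(clusters = list(list(n_sds = 4, n_ca = 0,
                                                geometry = "disc"))),
               "sphere")
  expect_error(config_spec(clusters = list(list(n_sds = 4, n_ca = 0,
                                                geometry = "sphere",
                                                radius = 80)), box = 200),
               "quarter")
  expect_error(config_spec(free_sds = 2, planted_condensed = 5, n_na = 2),
               "cannot exceed")
  expect_error(config_spec(), "at least one surfactant")
  # a box too small for the requested aggregates fails loudly
  big <- config_spec(clusters = list(list(n_sds = 20, n_ca = 20,
                                          geometry = "rod", radius = 3)),
                     box = 150, seed = 1)
  expect_error(build_configuration(big), "too large|Infeasible")
})

test_that("toy dynamics conserves molecules, respects the box and is null without attraction", {
  spec0 <- toy_sim_spec(n_sds = 10, n_ca = 10, attraction = 0,
                        n_steps = 3000, stride = 300, seed = 3)
  traj0 <- run_toy_aggregation(spec0)
  comps <- lapply(traj0$frames, function(f) {
    table(dplyr::distinct(f$beads, molecule_id, kind)$kind)
  })
  expect_true(all(vapply(comps[-1], identical, logical(1), comps[[1]])))
  for (f in traj0$frames) {
    expect_true(all(f$beads$x >= 0 & f$beads$x < f$box))
    expect_true(all(f$beads$y >= 0 & f$beads$y < f$box))
    expect_true(all(f$beads$z >= 0 & f$beads$z < f$box))
  }
  # without the hydrophobic attraction the dispersion stays molecular:
  # no persistent aggregates, only transient contact pairs
  last3 <- lapply(tail(traj0$frames, 3), find_clusters)
  noc_end <- mean(vapply(last3, function(a) a$n_clusters, numeric(1)))
  expect_gt(noc_end, 0.75 * 20)
  # mean aggregate size stays near 1 (transient contacts only)
  expect_lt(mean(20 / vapply(last3, function(a) a$n_clusters, numeric(1))),
            1.5)
})

test_that("attractive toy dynamics aggregates and enriches SDS in the core", {
  spec <- toy_sim_spec(n_sds = 15, n_ca = 15, n_steps = 12000,
                       stride = 400, seed = 4)
  traj <- run_toy_aggregation(spec)
  noc <- vapply(traj$frames, function(f) find_clusters(f)$n_clusters,
                numeric(1))
  expect_lt(mean(tail(noc, 5)), mean(head(noc, 3)))
  last <- find_clusters(traj$frames[[length(traj$frames)]])
  big <- last$clusters[which.max(last$clusters$size), ]
  expect_gt(big$size, 1)
  expect_gte(big$sds_fraction, 0.5)
})
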