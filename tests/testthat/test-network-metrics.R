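# Seven colony-level metrics and the disconnected-network correction.

test_that("local metrics match closed forms", {
  W <- matrix(0.5, 4, 4); diag(W) <- 0
  dimnames(W) <- list(letters[1:4], letters[1:4])
  m <- local_metrics(as_daily_network(W))
  expect_equal(m$mean_weighted_degree, 1.5)
  expect_equal(m$mean_binary_degree, 3)
  expect_equal(m$mean_edge_weight, 0.5)
  z <- as_daily_network(matrix(0, 3, 3, dimnames = list(letters[1:3],
                                                        letters[1:3])))
  mz <- local_metrics(z)
  expect_equal(unlist(mz), c(mean_weighted_degree = 0,
                             mean_binary_degree = 0, mean_edge_weight = 0))
  expect_warning(local_metrics(as_daily_network(matrix(0, 1, 1))), "fewer")
})

test_that("intermediate metrics match closed forms", {
  W <- matrix(0.3, 4, 4); diag(W) <- 0
  expect_equal(intermediate_metrics(as_daily_network(W))$cv_edge_weight, 0)
  # 5 nodes, 4 edges present -> density 0.4
  W5 <- matrix(0, 5, 5)
  W5[1, 2] <- W5[2, 1] <- 0.2
  W5[2, 3] <- W5[3, 2] <- 0.4
  W5[3, 4] <- W5[4, 3] <- 0.1
  W5[4, 5] <- W5[5, 4] <- 0.9
  expect_equal(intermediate_metrics(as_daily_network(W5))$edge_density, 0.4)
  # all-zero bird excluded from the CV average
  W0 <- W5; W0[1, 2] <- W0[2, 1] <- 0
  im <- intermediate_metrics(as_daily_network(W0))
  expect_equal(im$n_cv_excluded, 1)
})

test_that("global metrics match hand enumeration on a 3-node chain", {
  W <- matrix(0, 3, 3, dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  W["A", "B"] <- W["B", "A"] <- 0.5
  W["B", "C"] <- W["C", "B"] <- 0.5
  g <- weighted_global_metrics(as_daily_network(W))
  expect_equal(g$mean_path_length, (0.5 + 0.5 + 1.0) / 3)
  expect_equal(g$diameter, 1.0)
  # complete graph with equal weights: both equal the weight
  Wc <- matrix(0.4, 4, 4); diag(Wc) <- 0
  gc <- weighted_global_metrics(as_daily_network(Wc))
  expect_equal(gc$mean_path_length, 0.4)
  expect_equal(gc$diameter, 0.4)
})

test_that("all seven metrics match exhaustive oracles on random graphs", {
  for (seed in 1:40) {
    n <- sample(4:8, 1)
    W <- make_random_W(n, seed, p_edge = runif(1, 0.2, 0.9))
    net <- as_daily_network(W)
    lo <- suppressWarnings(local_metrics(net))
    io <- suppressWarnings(intermediate_metrics(net))
    go <- suppressWarnings(weighted_global_metrics(net))
    olo <- oracle_local(W)
    oio <- oracle_intermediate(W)
    ogo <- oracle_global(W)
    expect_equal(lo$mean_weighted_degree, olo$mean_weighted_degree,
                 tolerance = 1e-12)
    expect_equal(lo$mean_binary_degree, olo$mean_binary_degree,
                 tolerance = 1e-12)
    expect_equal(lo$mean_edge_weight, olo$mean_edge_weight,
                 tolerance = 1e-12)
    expect_equal(io$cv_edge_weight, oio$cv_edge_weight, tolerance = 1e-12)
    expect_equal(io$edge_density, oio$edge_density, tolerance = 1e-12)
    expect_equal(go$mean_path_length, ogo$mean_path_length,
                 tolerance = 1e-12)
    expect_equal(go$diameter, ogo$diameter, tolerance = 1e-12)
  }
})

test_that("study smallest edge weight scans all networks of a type", {
  W1 <- matrix(0, 3, 3); W1[1, 2] <- W1[2, 1] <- 0.2
  W2 <- matrix(0, 3, 3); W2[1, 3] <- W2[3, 1] <- 0.05
  W2[1, 2] <- W2[2, 1] <- 0.4
  W0 <- matrix(0, 3, 3)
  nets <- list(as_daily_network(W1), as_daily_network(W2),
               as_daily_network(W0))
  expect_equal(study_smallest_edge_weight(nets, "interaction"), 0.05)
  # oracle: flat scan over the long-format edge table
  allw <- unlist(lapply(nets, function(n) n$W[upper.tri(n$W)]))
  expect_equal(study_smallest_edge_weight(nets, "interaction"),
               min(allw[allw > 0]))
  expect_error(study_smallest_edge_weight(list(as_daily_network(W0)),
                                          "interaction"), "no positive")
})

test_that("connected networks need no correction", {
  W <- make_random_W(6, 5, p_edge = 1)
  net <- as_daily_network(W)
  cg <- corrected_global_metrics(net, 0.1, n_reps = 5, seed = 1)
  g <- weighted_global_metrics(net)
  expect_equal(cg$mean_path_length, g$mean_path_length)
  expect_equal(cg$diameter, g$diameter)
  expect_equal(cg$n_components, 1)
})

test_that("the two-cluster worked example corrects the diameter to 0.6", {
  W <- matrix(0, 3, 3, dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  W["A", "B"] <- W["B", "A"] <- 0.5
  net <- as_daily_network(W)
  cg <- corrected_global_metrics(net, 0.1, n_reps = 50, seed = 42)
  expect_equal(cg$diameter_raw, 0.5)
  # exhaustive enumeration: whichever of A/B is joined to C, the joined
  # network has paths {0.5, 0.1, 0.6} -> diameter 0.6 in every repetition
  expect_equal(cg$diameter, 0.6, tolerance = 1e-12)
  # mean path on the join is always (0.5+0.1+0.6)/3 = 0.4
  expect_equal(cg$mean_path_length, 0.5 + (0.4 - 0.5), tolerance = 1e-12)
  # invariant to the seed because every join choice gives the same value
  cg2 <- corrected_global_metrics(net, 0.1, n_reps = 7, seed = 999)
  expect_equal(cg2$diameter, cg$diameter)
})

test_that("the correction is deterministic under a fixed seed", {
  W <- make_random_W(8, 77, p_edge = 0.2)
  net <- as_daily_network(W)
  if (weighted_global_metrics(net)$n_components > 1) {
    a <- corrected_global_metrics(net, 0.05, n_reps = 30, seed = 11)
    b <- corrected_global_metrics(net, 0.05, n_reps = 30, seed = 11)
    expect_identical(a, b)
  }
  expect_error(corrected_global_metrics(net, 0), "smallest_edge_weight")
})

test_that("corrected diameter never falls below the raw value", {
  for (seed in 1:15) {
    W <- make_random_W(7, seed + 300, p_edge = 0.25)
    net <- as_daily_network(W)
    g <- suppressWarnings(weighted_global_metrics(net))
    if (is.na(g$diameter)) next
    cg <- suppressWarnings(
      corrected_global_metrics(net, 0.02, n_reps = 20, seed = seed))
    expect_gte(cg$diameter, g$diameter - 1e-12)
  }
})

test_that("path metrics scale linearly with the weights", {
  W <- make_random_W(7, 9, p_edge = 0.3)
  net <- as_daily_network(W)
  netk <- as_daily_network(3 * W)
  a <- suppressWarnings(corrected_global_metrics(net, 0.05, n_reps = 25,
                                                 seed = 4))
  b <- suppressWarnings(corrected_global_metrics(netk, 0.15, n_reps = 25,
                                                 seed = 4))
  expect_equal(3 * a$mean_path_length, b$mean_path_length, tolerance = 1e-10)
  expect_equal(3 * a$diameter, b$diameter, tolerance = 1e-10)
})

test_that("metric_table is stable under network list reordering", {
  sim <- simulate_study(tiny_config(seed = 44L, frames_per_day = 20))
  nets <- build_study_networks(sim$detections)
  t1 <- metric_table(nets, n_reps = 10, seed = 2)
  t2 <- metric_table(rev(nets), n_reps = 10, seed = 2)
  t2 <- t2[match(paste(t1$colony_id, t1$date, t1$net_type),
                 paste(t2$colony_id, t2$date, t2$net_type)), ]
  rownames(t2) <- NULL
  expect_equal(t1, t2)
})
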