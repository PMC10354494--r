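# Strict-SRI interaction networks and SRI association networks.

frame_recs <- function(x_px, birds = NULL, camera = "sp1") {
  n <- length(x_px)
  data.frame(colony_id = "c1", date = "2017-03-01", frame_id = 1L,
             camera_id = camera, location_type = "social_perch",
             bird_id = birds %||% sprintf("b%d", seq_len(n)),
             x_px = as.integer(x_px), stringsAsFactors = FALSE)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("clumping uses a strict 80-pixel threshold", {
  expect_equal(nrow(detect_clumps(frame_recs(c(100, 179)))), 1)  # 79 apart
  expect_equal(nrow(detect_clumps(frame_recs(c(100, 180)))), 0)  # 80 apart
  expect_equal(nrow(detect_clumps(frame_recs(c(100, 100)))), 1)
  three <- detect_clumps(frame_recs(c(0, 50, 120)))
  expect_equal(nrow(three), 2)  # (1,2) and (2,3), not (1,3)
  expect_error(detect_clumps(frame_recs(c(NA, 10))), "x_px")
})

test_that("birds on different perch cameras never clump but still count d", {
  recs <- rbind(frame_recs(100, "a", camera = "sp1"),
                frame_recs(110, "b", camera = "sp2"))
  expect_error(detect_clumps(recs), "single frame")
  cnt <- accumulate_interaction_counts(recs)
  expect_equal(cnt$x, 0L)
  expect_equal(cnt$d, 0L)  # never on the same perch either
})

test_that("interaction counts follow the strict-SRI definitions", {
  # 20 frames co-present on sp1, clumped in 5 of them; 7 frames b1 alone
  rows <- list()
  for (f in 1:20) {
    dx <- if (f <= 5) 30L else 200L
    rows[[f]] <- data.frame(colony_id = "c1", date = "2017-03-01",
                            frame_id = f, camera_id = "sp1",
                            location_type = "social_perch",
                            bird_id = c("b1", "b2"),
                            x_px = c(400L, 400L + dx),
                            stringsAsFactors = FALSE)
  }
  for (f in 21:27) {
    rows[[f]] <- data.frame(colony_id = "c1", date = "2017-03-01",
                            frame_id = f, camera_id = "sp1",
                            location_type = "social_perch", bird_id = "b1",
                            x_px = 10L, stringsAsFactors = FALSE)
  }
  cnt <- accumulate_interaction_counts(do.call(rbind, rows))
  expect_equal(cnt$x, 5L)
  expect_equal(cnt$d, 20L)  # solo frames do not enter the denominator
  expect_equal(ratio_index(cnt), 0.25)
})

test_that("association counts follow the SRI definitions", {
  rows <- list()
  for (f in 1:10)  # both on f1
    rows[[length(rows) + 1]] <- data.frame(
      colony_id = "c1", date = "2017-03-01", frame_id = f, camera_id = "f1",
      location_type = "feeder", bird_id = c("a", "b"), x_px = NA_integer_,
      stringsAsFactors = FALSE)
  for (f in 11:40)  # a alone
    rows[[length(rows) + 1]] <- data.frame(
      colony_id = "c1", date = "2017-03-01", frame_id = f, camera_id = "f1",
      location_type = "feeder", bird_id = "a", x_px = NA_integer_,
      stringsAsFactors = FALSE)
  # different tables in the same frame: d, not x
  rows[[length(rows) + 1]] <- data.frame(
    colony_id = "c1", date = "2017-03-01", frame_id = 41L,
    camera_id = c("f1", "f2"), location_type = "feeder",
    bird_id = c("a", "b"), x_px = NA_integer_, stringsAsFactors = FALSE)
  cnt <- accumulate_association_counts(do.call(rbind, rows))
  expect_equal(cnt$x, 10L)
  expect_equal(cnt$d, 41L)
})

test_that("ratio index handles edge cases and rejects impossible counts", {
  expect_equal(ratio_index(5, 20), 0.25)
  expect_equal(ratio_index(7, 7), 1)
  expect_equal(ratio_index(0, 0), 0)
  expect_error(ratio_index(3, 2), "x > d")
  expect_error(ratio_index(-1, 2), "non-negative")
})

test_that("daily networks match the frame-by-frame oracle on random fixtures", {
  for (seed in 1:25) {
    n_birds <- sample(3:6, 1)
    recs <- make_random_detections(n_birds, n_frames = sample(20:100, 1),
                                   seed = seed)
    for (ty in c("interaction", "association")) {
      net <- build_daily_network(recs, ty)
      Wo <- oracle_weight_matrix(recs, ty)
      if (!nrow(Wo)) {
        expect_equal(net$n_nodes, 0)
        next
      }
      expect_identical(rownames(net$W), rownames(Wo))
      expect_equal(net$W, Wo, tolerance = 0)
      expect_true(isSymmetric(net$W))
      expect_true(all(diag(net$W) == 0))
      expect_true(all(net$W >= 0 & net$W <= 1))
    }
  }
})

test_that("record order never changes the network", {
  recs <- make_random_detections(5, 60, seed = 101)
  net1 <- build_daily_network(recs, "interaction")
  set.seed(1)
  net2 <- build_daily_network(recs[sample(nrow(recs)), ], "interaction")
  expect_equal(net1$W, net2$W)
})

test_that("degenerate days are built but flagged", {
  one <- frame_recs(100, "solo")
  net <- build_daily_network(one, "interaction")
  expect_true(net$flagged)
  expect_equal(net$n_nodes, 1)
  expect_equal(dim(net$W), c(1, 1))
  # feeder-only day yields an empty interaction network
  fd <- data.frame(colony_id = "c1", date = "2017-03-01", frame_id = 1L,
                   camera_id = "f1", location_type = "feeder",
                   bird_id = "a", x_px = NA_integer_,
                   stringsAsFactors = FALSE)
  expect_equal(build_daily_network(fd, "interaction")$n_nodes, 0)
})

test_that("study networks split per colony-day and context", {
  sim <- simulate_study(tiny_config(seed = 6L))
  nets <- build_study_networks(sim$detections)
  idx <- t(vapply(nets, function(n) c(n$colony_id, n$date, n$net_type),
                  character(3)))
  expect_false(anyDuplicated(idx) > 0)
  et <- edge_table(nets)
  expect_true(all(et$weight >= 0 & et$weight <= 1))
  expect_true(all(et$x <= et$d))
})
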