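# Independent brute-force oracles used across the suite. These deliberately
# re-derive every quantity with naive frame-by-frame / element-wise
# enumeration, sharing no code with the package implementation.

# Dyadic counts by explicit frame-by-frame enumeration.
oracle_interaction_counts <- function(day_records, threshold_px = 80) {
  recs <- day_records[day_records$location_type %in%
                        c("social_perch", "copulation_perch"), , drop = FALSE]
  birds <- sort(unique(recs$bird_id))
  x <- d <- matrix(0L, length(birds), length(birds),
                   dimnames = list(birds, birds))
  for (cam in unique(recs$camera_id)) {
    rc <- recs[recs$camera_id == cam, , drop = FALSE]
    for (f in unique(rc$frame_id)) {
      rf <- rc[rc$frame_id == f, , drop = FALSE]
      if (nrow(rf) < 2) next
      for (i in 1:(nrow(rf) - 1)) for (j in (i + 1):nrow(rf)) {
        a <- rf$bird_id[i]; b <- rf$bird_id[j]
        if (a == b) next
        d[a, b] <- d[a, b] + 1L; d[b, a] <- d[a, b]
        if (abs(rf$x_px[i] - rf$x_px[j]) < threshold_px) {
          x[a, b] <- x[a, b] + 1L; x[b, a] <- x[a, b]
        }
      }
    }
  }
  list(birds = birds, x = x, d = d)
}

oracle_association_counts <- function(day_records) {
  recs <- day_records[day_records$location_type == "feeder", , drop = FALSE]
  birds <- sort(unique(recs$bird_id))
  x <- d <- matrix(0L, length(birds), length(birds),
                   dimnames = list(birds, birds))
  frames <- unique(recs$frame_id)
  for (f in frames) {
    rf <- recs[recs$frame_id == f, , drop = FALSE]
    for (ii in seq_along(birds)) for (jj in seq_along(birds)) {
      if (jj <= ii) next
      a <- birds[ii]; b <- birds[jj]
      at_a <- rf$camera_id[rf$bird_id == a]
      at_b <- rf$camera_id[rf$bird_id == b]
      if (length(at_a) || length(at_b)) {
        d[a, b] <- d[a, b] + 1L; d[b, a] <- d[a, b]
      }
      if (length(intersect(at_a, at_b))) {
        x[a, b] <- x[a, b] + 1L; x[b, a] <- x[a, b]
      }
    }
  }
  list(birds = birds, x = x, d = d)
}

# Oracle weight matrix (x/d, 0 when d = 0) for one colony-day and type.
oracle_weight_matrix <- function(day_records, net_type, threshold_px = 80) {
  cnt <- if (net_type == "interaction")
    oracle_interaction_counts(day_records, threshold_px)
  else oracle_association_counts(day_records)
  W <- matrix(0, length(cnt$birds), length(cnt$birds),
              dimnames = list(cnt$birds, cnt$birds))
  for (a in cnt$birds) for (b in cnt$birds) {
    if (a != b && cnt$d[a, b] > 0) W[a, b] <- cnt$x[a, b] / cnt$d[a, b]
  }
  W
}

# --- element-wise metric oracles on a weight matrix ---------------------

oracle_local <- function(W) {
  n <- nrow(W)
  wd <- bd <- numeric(n)
  for (i in 1:n) {
    for (j in 1:n) if (j != i) {
      wd[i] <- wd[i] + W[i, j]
      if (W[i, j] > 0) bd[i] <- bd[i] + 1
    }
  }
  s <- 0; np <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) { s <- s + W[i, j]; np <- np + 1 }
  list(mean_weighted_degree = mean(wd), mean_binary_degree = mean(bd),
       mean_edge_weight = s / np)
}

oracle_intermediate <- function(W) {
  n <- nrow(W)
  cvs <- c()
  for (i in 1:n) {
    w <- W[i, setdiff(1:n, i)]
    if (mean(w) > 0) cvs <- c(cvs, sd(w) / mean(w))
  }
  ne <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) if (W[i, j] > 0) ne <- ne + 1
  list(cv_edge_weight = if (length(cvs)) mean(cvs) else NA_real_,
       edge_density = ne / (n * (n - 1) / 2))
}

# Connected components by hand-rolled BFS on the binarized graph.
oracle_components <- function(W) {
  n <- nrow(W)
  comp <- rep(NA_integer_, n)
  k <- 0
  for (s in 1:n) {
    if (!is.na(comp[s])) next
    k <- k + 1
    queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (!is.na(comp[v])) next
      comp[v] <- k
      queue <- c(queue, which(W[v, ] > 0 & is.na(comp)))
    }
  }
  comp
}

# All-pairs shortest paths (weights as costs) by Floyd-Warshall.
oracle_shortest_paths <- function(W) {
  n <- nrow(W)
  D <- matrix(Inf, n, n); diag(D) <- 0
  for (i in 1:n) for (j in 1:n) if (i != j && W[i, j] > 0) D[i, j] <- W[i, j]
  for (k in 1:n) for (i in 1:n) for (j in 1:n)
    if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  D
}

# Raw global metrics restricted to the largest component.
oracle_global <- function(W) {
  comp <- oracle_components(W)
  sizes <- table(comp)
  big <- as.integer(names(sizes)[which.max(sizes)])
  keep <- which(comp == big)
  if (length(keep) < 2)
    return(list(mean_path_length = NA_real_, diameter = NA_real_))
  D <- oracle_shortest_paths(W[keep, keep, drop = FALSE])
  vals <- D[upper.tri(D)]
  list(mean_path_length = mean(vals), diameter = max(vals))
}

# --- random fixtures ----------------------------------------------------

# Random one-day detection table: birds roam between two perch cameras,
# two feeding tables and "absent", with random perch pixel positions.
make_random_detections <- function(n_birds, n_frames, seed,
                                   perch_x_max = 400) {
  set.seed(seed)
  birds <- sprintf("b%02d", seq_len(n_birds))
  rows <- list()
  places <- c("sp1", "sp2", "cp1", "f1", "f2", "none", "none")
  loc_of <- c(sp1 = "social_perch", sp2 = "social_perch",
              cp1 = "copulation_perch", f1 = "feeder", f2 = "feeder")
  for (f in seq_len(n_frames)) {
    at <- sample(places, n_birds, replace = TRUE)
    for (i in seq_len(n_birds)) {
      if (at[i] == "none") next
      rows[[length(rows) + 1]] <- data.frame(
        colony_id = "cx", date = "2017-03-01", frame_id = f,
        camera_id = at[i], location_type = loc_of[[at[i]]],
        bird_id = birds[i],
        x_px = if (loc_of[[at[i]]] == "feeder") NA_integer_
        else sample.int(perch_x_max, 1) - 1L,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

# Random symmetric weight matrix, optionally sparse/disconnected.
make_random_W <- function(n, seed, p_edge = 0.5) {
  set.seed(seed)
  W <- matrix(0, n, n, dimnames = list(sprintf("b%d", 1:n),
                                       sprintf("b%d", 1:n)))
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    if (runif(1) < p_edge) W[i, j] <- W[j, i] <- round(runif(1, 0.05, 1), 3)
  }
  W
}

as_daily_network <- function(W, net_type = "interaction") {
  structure(list(colony_id = "cx", date = "2017-03-01", net_type = net_type,
                 nodes = rownames(W), W = W, counts = NULL,
                 n_nodes = nrow(W), flagged = nrow(W) < 2),
            class = "daily_network")
}

# Small deterministic detection fixture used by io tests.
fixture_detections <- function() {
  data.frame(
    colony_id = "c1", date = "2017-03-01",
    frame_id = c(1L, 1L, 2L), camera_id = c("sp1", "sp1", "f1"),
    location_type = c("social_perch", "social_perch", "feeder"),
    bird_id = c("a", "b", "a"),
    x_px = c(100L, 150L, NA_integer_), stringsAsFactors = FALSE)
}

tiny_config <- function(...) {
  args <- utils::modifyList(
    list(n_years = 1, colonies_per_year = 2, birds_per_colony = 5,
         days_pre = 2, days_post_by_year = 2, frames_per_day = 30,
         seed = 99L),
    list(...))
  do.call(synthetic_config, args)
}
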