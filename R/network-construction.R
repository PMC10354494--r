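# Daily social network construction.
#
# Interaction networks (perch cameras): edge = strict simple ratio index,
#   frames clumped / frames both detected on the same perch camera,
# where clumping means two barcodes < 80 px apart in one frame. The strict
# denominator isolates the choice to interact from mere co-presence.
#
# Association networks (feeding tables): edge = simple ratio index,
#   frames both on the same table / frames at least one at any table
# (gambit of the group, frame = sampling period).

#' Clumped pairs within one frame of one perch camera
#'
#' @param frame_records detection records sharing colony, date, frame and
#'   camera; `x_px` must be present.
#' @param threshold_px clumping threshold; pairs strictly closer than this
#'   many pixels are clumped (default 80, one body-width).
#' @return data.frame with columns `bird_a`, `bird_b` (unordered, a < b).
#' @export
detect_clumps <- function(frame_records, threshold_px = 80) {
  if (nrow(frame_records)) {
    if (length(unique(paste(frame_records$colony_id, frame_records$date,
                            frame_records$frame_id,
                            frame_records$camera_id))) != 1)
      stop_cn("detect_clumps expects records of a single frame and camera")
    if (any(is.na(frame_records$x_px)))
      stop_cn("detect_clumps requires x_px on every record")
  }
  birds <- frame_records$bird_id
  x <- frame_records$x_px
  out <- list(); n <- length(birds)
  if (n >= 2) {
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      if (abs(x[i] - x[j]) < threshold_px) {
        ab <- sort(c(birds[i], birds[j]))
        out[[length(out) + 1]] <- ab
      }
    }
  }
  if (!length(out))
    return(data.frame(bird_a = character(), bird_b = character(),
                      stringsAsFactors = FALSE))
  m <- do.call(rbind, out)
  unique(data.frame(bird_a = m[, 1], bird_b = m[, 2],
                    stringsAsFactors = FALSE))
}

# All unordered pairs of `birds` as a data.frame skeleton with x = d = 0.
empty_dyads <- function(birds) {
  birds <- sort(unique(birds))
  if (length(birds) < 2)
    return(data.frame(bird_a = character(), bird_b = character(),
                      x = integer(), d = integer(), stringsAsFactors = FALSE))
  prs <- utils::combn(birds, 2)
  data.frame(bird_a = prs[1, ], bird_b = prs[2, ], x = 0L, d = 0L,
             stringsAsFactors = FALSE)
}

# Presence matrix birds x scenes from parallel id vectors.
presence_matrix <- function(bird, scene) {
  b <- factor(bird); s <- factor(scene)
  m <- matrix(0L, nlevels(b), nlevels(s),
              dimnames = list(levels(b), levels(s)))
  m[cbind(as.integer(b), as.integer(s))] <- 1L
  m
}

fill_pair_counts <- function(skel, mat, column) {
  idx <- cbind(match(skel$bird_a, rownames(mat)),
               match(skel$bird_b, rownames(mat)))
  ok <- !is.na(idx[, 1]) & !is.na(idx[, 2])
  skel[[column]][ok] <- as.integer(mat[idx[ok, , drop = FALSE]])
  skel
}

#' Dyadic counts for the interaction (clumping) index
#'
#' For every unordered pair of birds detected on a perch that colony-day:
#' `x` = frames in which the pair was clumped, `d` = frames in which both
#' were detected on the same perch camera (the strict-SRI denominator).
#'
#' @param day_records perch detection records of one colony-day.
#' @param threshold_px clumping threshold in pixels.
#' @return data.frame `bird_a`, `bird_b`, `x`, `d`.
#' @export
accumulate_interaction_counts <- function(day_records, threshold_px = 80) {
  recs <- day_records[day_records$location_type %in% PERCH_TYPES, ,
                      drop = FALSE]
  skel <- empty_dyads(recs$bird_id)
  if (!nrow(skel) || !nrow(recs)) return(skel)
  if (any(is.na(recs$x_px)))
    stop_cn("perch records with missing x_px")
  scene <- paste(recs$camera_id, recs$frame_id, sep = "\r")
  pres <- presence_matrix(recs$bird_id, scene)
  skel <- fill_pair_counts(skel, tcrossprod(pres), "d")
  # clumped frames: enumerate scenes with >= 2 birds
  xs <- matrix(0L, nrow(pres), nrow(pres),
               dimnames = list(rownames(pres), rownames(pres)))
  idx_by_scene <- split(seq_len(nrow(recs)), scene)
  for (ix in idx_by_scene) {
    if (length(ix) < 2) next
    xv <- recs$x_px[ix]; bv <- recs$bird_id[ix]
    for (i in seq_len(length(ix) - 1)) for (j in (i + 1):length(ix)) {
      if (bv[i] != bv[j] && abs(xv[i] - xv[j]) < threshold_px) {
        xs[bv[i], bv[j]] <- xs[bv[i], bv[j]] + 1L
        xs[bv[j], bv[i]] <- xs[bv[j], bv[i]] + 1L
      }
    }
  }
  skel <- fill_pair_counts(skel, xs, "x")
  skel
}

#' Dyadic counts for the foraging association index
#'
#' For every unordered pair of birds detected at a feeder that colony-day:
#' `x` = frames in which both were on the same feeding table, `d` = frames
#' in which at least one of the two was detected at any feeding table.
#'
#' @param day_records feeder detection records of one colony-day.
#' @return data.frame `bird_a`, `bird_b`, `x`, `d`.
#' @export
accumulate_association_counts <- function(day_records) {
  recs <- day_records[day_records$location_type == "feeder", , drop = FALSE]
  skel <- empty_dyads(recs$bird_id)
  if (!nrow(skel) || !nrow(recs)) return(skel)
  # same-table co-occurrence
  same_tab <- tcrossprod(presence_matrix(
    recs$bird_id, paste(recs$frame_id, recs$camera_id, sep = "\r")))
  # any-feeder frame presence
  anyf <- presence_matrix(recs$bird_id, recs$frame_id)
  anyf[anyf > 1] <- 1L
  both_any <- tcrossprod(anyf)
  n_frames <- rowSums(anyf)
  skel <- fill_pair_counts(skel, same_tab, "x")
  ia <- match(skel$bird_a, names(n_frames))
  ib <- match(skel$bird_b, names(n_frames))
  skel$d <- as.integer(n_frames[ia] + n_frames[ib] -
                         both_any[cbind(ia, ib)])
  # a bird seen at two tables in one frame would double-count x; cap at d
  skel$x <- pmin(skel$x, skel$d)
  skel
}

#' Simple ratio index from dyadic counts
#'
#' `x / d` with the convention that dyads never sampled together (`d = 0`)
#' get weight 0 (no data, no edge).
#'
#' @param x joint count(s).
#' @param d denominator count(s); may be a `DyadCounts` data.frame in which
#'   case `x` is ignored.
#' @return numeric weight(s) in `[0, 1]`.
#' @export
ratio_index <- function(x, d) {
  if (is.data.frame(x)) { d <- x$d; x <- x$x }
  if (any(is.na(x)) || any(is.na(d)) || any(x < 0) || any(d < 0))
    stop_cn("ratio_index: counts must be non-negative")
  if (any(x > d)) stop_cn("ratio_index: x > d for some dyad")
  ifelse(d > 0, x / d, 0)
}

#' Build one daily social network
#'
#' Nodes are the birds detected that day at the network's location class
#' (perches for `interaction`, feeders for `association`); `W` is the
#' symmetric matrix of ratio-index edge weights with zero diagonal.
#'
#' @param day_records detection records of one colony-day.
#' @param net_type `"interaction"` or `"association"`.
#' @param threshold_px clumping threshold (interaction networks).
#' @return object of class `daily_network`: list with `colony_id`, `date`,
#'   `net_type`, `nodes`, `W`, `counts`, `n_nodes`, `flagged` (TRUE when
#'   fewer than 2 nodes were detected).
#' @export
build_daily_network <- function(day_records, net_type = c("interaction",
                                                          "association"),
                                threshold_px = 80) {
  net_type <- match.arg(net_type)
  day_records <- validate_detections(day_records)
  cd <- unique(day_records[, c("colony_id", "date")])
  if (nrow(cd) > 1)
    stop_cn("build_daily_network expects records of a single colony-day")
  keep <- if (net_type == "interaction")
    day_records$location_type %in% PERCH_TYPES
  else day_records$location_type == "feeder"
  recs <- day_records[keep, , drop = FALSE]
  nodes <- sort(unique(recs$bird_id))
  counts <- if (net_type == "interaction")
    accumulate_interaction_counts(recs, threshold_px)
  else accumulate_association_counts(recs)
  W <- matrix(0, length(nodes), length(nodes),
              dimnames = list(nodes, nodes))
  if (nrow(counts)) {
    wts <- ratio_index(counts)
    ia <- match(counts$bird_a, nodes); ib <- match(counts$bird_b, nodes)
    W[cbind(ia, ib)] <- wts
    W[cbind(ib, ia)] <- wts
  }
  structure(list(colony_id = if (nrow(cd)) cd$colony_id else NA_character_,
                 date = if (nrow(cd)) cd$date else NA_character_,
                 net_type = net_type, nodes = nodes, W = W, counts = counts,
                 n_nodes = length(nodes), flagged = length(nodes) < 2),
            class = "daily_network")
}

#' @export
print.daily_network <- function(x, ...) {
  cat(sprintf("<daily_network> %s %s [%s]: %d nodes, %d edges\n",
              x$colony_id, x$date, x$net_type, x$n_nodes,
              sum(x$W[upper.tri(x$W)] > 0)))
  invisible(x)
}

#' Build both daily networks for every colony-day of a study
#'
#' @param records validated detection records (whole study).
#' @param threshold_px clumping threshold.
#' @return list of `daily_network` objects named `colony|date|type`; only
#'   colony-day-types with at least one detection are present.
#' @export
build_study_networks <- function(records, threshold_px = 80) {
  records <- validate_detections(records)
  out <- list()
  for (key in unique(paste(records$colony_id, records$date, sep = "|"))) {
    parts <- strsplit(key, "|", fixed = TRUE)[[1]]
    day <- records[records$colony_id == parts[1] &
                     records$date == parts[2], , drop = FALSE]
    if (any(day$location_type %in% PERCH_TYPES))
      out[[paste(key, "interaction", sep = "|")]] <-
        build_daily_network(day, "interaction", threshold_px)
    if (any(day$location_type == "feeder"))
      out[[paste(key, "association", sep = "|")]] <-
        build_daily_network(day, "association")
  }
  out
}

#' Long-format edge table of a set of daily networks
#'
#' @param networks list of `daily_network` objects.
#' @return data.frame `colony_id,date,net_type,bird_a,bird_b,weight,x,d`.
#' @export
edge_table <- function(networks) {
  rows <- lapply(networks, function(net) {
    if (!nrow(net$counts)) return(NULL)
    data.frame(colony_id = net$colony_id, date = net$date,
               net_type = net$net_type, net$counts,
               weight = ratio_index(net$counts), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(colony_id = character(), date = character(),
                      net_type = character(), bird_a = character(),
                      bird_b = character(), x = integer(), d = integer(),
                      weight = numeric(), stringsAsFactors = FALSE)
  out <- out[, c("colony_id", "date", "net_type", "bird_a", "bird_b",
                 "weight", "x", "d")]
  rownames(out) <- NULL
  out
}
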