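# Synthetic detection-stream generator.
#
# Emulates an aviary tracking system: barcode-tagged birds photographed on
# perches (two social perches, one copulation perch) and at feeding tables,
# with a latent additive sociality model on the log-odds scale
#   logit P(clump | i,j co-present on a perch, colony c, day d)
#     = intercept + u_c + v_d + g_i + g_j + p_ij + sum_k beta_k x_k(c,d)
# and an analogous bout model for joining a feeding table. Camera dropout
# thins every emitted detection with a per-colony-day retention rate.

#' Configuration for a synthetic tracking study
#'
#' Defaults mirror the study design the pipeline is built for: 4 colonies per
#' year over 3 years, 28 birds per colony, the last 10 pre-breeding days and
#' 14/10/28 post-breeding days per year, daily frames at perch and feeder
#' cameras. Latent effect sizes are illustrative (no field calibration
#' exists on this scale); see the methods vignette.
#'
#' @param n_years number of study years.
#' @param colonies_per_year colonies observed in parallel each year.
#' @param birds_per_colony starting colony size (>= 2).
#' @param days_pre pre-breeding days per colony.
#' @param days_post_by_year integer vector, post-breeding days per year
#'   (length `n_years`).
#' @param frames_per_day camera frames per day (per camera).
#' @param sd_colony,sd_date,sd_individual,sd_dyad standard deviations of the
#'   latent colony, date, individual gregariousness and pair-bond effects
#'   (log-odds scale, all >= 0).
#' @param beta named numeric vector of covariate effects on the latent
#'   log-odds scale; names among `group_size`, `temp_c`, `humidity_pct`,
#'   `cloud_okta` (applied to within-study z-scores) and `age2`,
#'   `aspect_southwest`, `aviary_large` (0/1 indicators).
#' @param intercept baseline clumping log-odds for a co-present dyad.
#' @param feeder_intercept baseline log-odds that a bird joins a feeding
#'   bout in a given frame.
#' @param detection_rate_range interval in (0, 1]; each colony-day draws its
#'   camera retention rate uniformly from it ("camera detections" driver).
#' @param removal_prob per-bird per-day probability of permanent removal
#'   (death / veterinary), driving group-size variation.
#' @param n_masked_pre_association number of pre-breeding colony-days whose
#'   feeder records are dropped (emulating camera failures).
#' @param perch_width_px pixel width of a perch image.
#' @param clump_threshold_px clumping distance; pair separations are drawn
#'   strictly below it for clumped pairs and at/above it otherwise, so the
#'   pixel rule is exactly recoverable.
#' @param seed master integer seed (see [derive_seed()]).
#' @return an object of class `synthetic_config` (a validated list).
#' @export
synthetic_config <- function(n_years = 3,
                             colonies_per_year = 4,
                             birds_per_colony = 28,
                             days_pre = 10,
                             days_post_by_year = c(14, 10, 28),
                             frames_per_day = 2000,
                             sd_colony = 0.5,
                             sd_date = 0.3,
                             sd_individual = 0.3,
                             sd_dyad = 0.7,
                             beta = c(group_size = -0.2, temp_c = 0.2,
                                      humidity_pct = -0.1, cloud_okta = -0.15,
                                      age2 = 0.3, aspect_southwest = -0.1,
                                      aviary_large = -0.2),
                             intercept = -1,
                             feeder_intercept = -1.2,
                             detection_rate_range = c(0.5, 0.9),
                             removal_prob = 0.001,
                             n_masked_pre_association = 0,
                             perch_width_px = 2000,
                             clump_threshold_px = 80,
                             seed = 1L) {
  cfg <- list(n_years = as.integer(n_years),
              colonies_per_year = as.integer(colonies_per_year),
              birds_per_colony = as.integer(birds_per_colony),
              days_pre = as.integer(days_pre),
              days_post_by_year = as.integer(days_post_by_year),
              frames_per_day = as.integer(frames_per_day),
              sd_colony = sd_colony, sd_date = sd_date,
              sd_individual = sd_individual, sd_dyad = sd_dyad,
              beta = beta, intercept = intercept,
              feeder_intercept = feeder_intercept,
              detection_rate_range = detection_rate_range,
              removal_prob = removal_prob,
              n_masked_pre_association = as.integer(n_masked_pre_association),
              perch_width_px = as.integer(perch_width_px),
              clump_threshold_px = as.integer(clump_threshold_px),
              seed = as.integer(seed))
  validate_synthetic_config(cfg)
  structure(cfg, class = "synthetic_config")
}

validate_synthetic_config <- function(cfg) {
  sds <- c(cfg$sd_colony, cfg$sd_date, cfg$sd_individual, cfg$sd_dyad)
  if (any(!is.finite(sds)) || any(sds < 0))
    stop_cn("all latent standard deviations must be finite and >= 0")
  if (cfg$birds_per_colony < 2)
    stop_cn("birds_per_colony must be >= 2")
  if (length(cfg$days_post_by_year) != cfg$n_years)
    stop_cn("days_post_by_year must have length n_years (%d)", cfg$n_years)
  dr <- cfg$detection_rate_range
  if (length(dr) != 2 || any(!is.finite(dr)) || dr[1] <= 0 || dr[2] > 1 ||
      dr[1] > dr[2])
    stop_cn("detection_rate_range must be an interval within (0, 1]")
  if (length(cfg$beta) && (is.null(names(cfg$beta)) ||
                           any(!nzchar(names(cfg$beta)))))
    stop_cn("beta must be a named numeric vector")
  if (any(!is.finite(cfg$beta)))
    stop_cn("beta contains non-finite covariate effects")
  known <- c("group_size", "temp_c", "humidity_pct", "cloud_okta",
             "age2", "aspect_southwest", "aviary_large")
  bad <- setdiff(names(cfg$beta), known)
  if (length(bad))
    stop_cn("unknown beta name(s): %s", paste(bad, collapse = ", "))
  if (cfg$days_pre < 0 || any(cfg$days_post_by_year < 0))
    stop_cn("day counts must be non-negative")
  if (cfg$days_pre + sum(cfg$days_post_by_year) == 0)
    stop_cn("study has zero days")
  invisible(cfg)
}

#' Study layout: one row per colony-day
#'
#' Deterministic scaffolding for a config: colony identifiers, calendar
#' dates (shared across colonies within a year, as for a single weather
#' station), seasons and years. Pre-breeding days start 1 March, the
#' post-breeding block 1 June of each study year.
#'
#' @param config a [synthetic_config()].
#' @return data.frame with columns `colony_id`, `year`, `season`, `date`.
#' @export
study_layout <- function(config) {
  years <- 2017L + seq_len(config$n_years) - 1L
  out <- list()
  for (yi in seq_along(years)) {
    y <- years[yi]
    cols <- sprintf("%d-C%02d", y, seq_len(config$colonies_per_year))
    pre <- if (config$days_pre > 0)
      as.character(as.Date(sprintf("%d-03-01", y)) + 0:(config$days_pre - 1))
    else character()
    npost <- config$days_post_by_year[yi]
    post <- if (npost > 0)
      as.character(as.Date(sprintf("%d-06-01", y)) + 0:(npost - 1))
    else character()
    dates <- c(pre, post)
    seasons <- c(rep("pre", length(pre)), rep("post", length(post)))
    out[[yi]] <- data.frame(
      colony_id = rep(cols, each = length(dates)),
      year = y,
      season = rep(seasons, times = length(cols)),
      date = rep(dates, times = length(cols)),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

# Membership (which birds are present on each colony-day) is simulated once
# from its own sub-stream so covariates and detections agree on group sizes.
# Removal risk accrues across calendar gaps between consecutive study days.
simulate_membership <- function(config) {
  layout <- study_layout(config)
  with_seed(derive_seed(config$seed, "membership"), {
    res <- list()
    for (col in unique(layout$colony_id)) {
      rows <- layout[layout$colony_id == col, ]
      rows <- rows[order(rows$date), ]
      birds <- sprintf("%s-b%02d", col, seq_len(config$birds_per_colony))
      present <- rep(TRUE, length(birds))
      prev_date <- NULL
      for (k in seq_len(nrow(rows))) {
        gap <- if (is.null(prev_date)) 1
        else as.integer(as.Date(rows$date[k]) - as.Date(prev_date))
        p_rem <- 1 - (1 - config$removal_prob)^gap
        drop <- present & (stats::runif(length(birds)) < p_rem)
        # never drop below 2 birds
        if (sum(present) - sum(drop) >= 2) present <- present & !drop
        res[[paste(col, rows$date[k], sep = "|")]] <- birds[present]
        prev_date <- rows$date[k]
      }
    }
    res
  })
}

#' Simulate daily external-driver covariates
#'
#' One row per colony-day: group size (from simulated membership), bird age
#' (1 year in odd study years, 2 in the second year, mirroring a
#' breed-and-replace husbandry cycle), daily mean temperature, humidity and
#' cloud cover (shared across colonies within a day, drawn uniformly from
#' the observed study ranges 0.0--25.6 degC, 48.1--92.7 % and 0--8 okta),
#' aviary aspect (random side per colony-year) and aviary floor area
#' (12 m2 in year 1, 24 m2 afterwards). `n_detections` is left `NA`;
#' the pipeline fills it from the emitted records.
#'
#' @param config a [synthetic_config()].
#' @param seed optional override of the covariate sub-stream seed.
#' @return data.frame of covariate rows (one per colony-day).
#' @export
simulate_covariates <- function(config, seed = NULL) {
  layout <- study_layout(config)
  membership <- simulate_membership(config)
  with_seed(seed %||% derive_seed(config$seed, "covariates"), {
    dates <- sort(unique(layout$date))
    weather <- data.frame(
      date = dates,
      temp_c = round(stats::runif(length(dates), 0.0, 25.6), 1),
      humidity_pct = round(stats::runif(length(dates), 48.1, 92.7), 1),
      cloud_okta = sample(0:8, length(dates), replace = TRUE),
      stringsAsFactors = FALSE)
    cy <- unique(layout[, c("colony_id", "year")])
    cy$aspect <- sample(c("northeast", "southwest"), nrow(cy), replace = TRUE)
    years <- sort(unique(layout$year))
    area_by_year <- stats::setNames(
      ifelse(seq_along(years) == 1, 12, 24), years)
    age_by_year <- stats::setNames(
      ifelse(seq_along(years) %% 2 == 0, 2L, 1L), years)
    out <- merge(layout, weather, by = "date", sort = FALSE)
    out <- merge(out, cy, by = c("colony_id", "year"), sort = FALSE)
    out$aviary_area_m2 <- as.numeric(area_by_year[as.character(out$year)])
    out$age_years <- as.integer(age_by_year[as.character(out$year)])
    out$group_size <- vapply(paste(out$colony_id, out$date, sep = "|"),
                             function(k) length(membership[[k]]), integer(1))
    out$n_detections <- NA_integer_
    out <- out[order(out$colony_id, out$date),
               c("colony_id", "date", "group_size", "age_years", "temp_c",
                 "humidity_pct", "cloud_okta", "aspect", "aviary_area_m2",
                 "n_detections", "season", "year")]
    rownames(out) <- NULL
    out
  })
}

# z-score used inside the generator's linear predictor (n-1 denominator).
zscore <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) rep(0, length(x)) else (x - mean(x)) / s
}

# Latent linear predictor contribution of the covariates, per colony-day.
covariate_eta <- function(covs, beta) {
  design <- cbind(group_size = zscore(covs$group_size),
                  temp_c = zscore(covs$temp_c),
                  humidity_pct = zscore(covs$humidity_pct),
                  cloud_okta = zscore(covs$cloud_okta),
                  age2 = as.numeric(covs$age_years == 2),
                  aspect_southwest = as.numeric(covs$aspect == "southwest"),
                  aviary_large = as.numeric(covs$aviary_area_m2 > 12))
  if (!length(beta)) return(rep(0, nrow(covs)))
  as.numeric(design[, names(beta), drop = FALSE] %*% beta)
}

#' Simulate a full tracking study
#'
#' Emits per-frame detection records for every colony-day. On each perch
#' camera each frame photographs one candidate dyad (drawn uniformly among
#' birds present that day); the dyad clumps with its latent probability, in
#' which case the two pixel positions are written strictly less than
#' `clump_threshold_px` apart, otherwise at least that far apart. Feeder
#' records come from a per-frame bout process in which each bird joins a
#' feeding table with its latent foraging probability (two tables when the
#' aviary is the doubled 24 m2 configuration, one otherwise). Every record
#' is then independently retained with the colony-day camera retention rate
#' drawn from `detection_rate_range`.
#'
#' @param config a [synthetic_config()].
#' @return list with elements `detections` (data.frame in the detections
#'   schema), `covariates` (see [simulate_covariates()]) and `ground_truth`
#'   (latent effects, retention rates, expected dyad clumping probabilities,
#'   masked colony-days, config echo).
#' @export
simulate_study <- function(config) {
  validate_synthetic_config(config)
  layout <- study_layout(config)
  membership <- simulate_membership(config)
  covs <- simulate_covariates(config)

  all_birds <- sort(unique(unlist(membership)))
  colonies <- unique(layout$colony_id)
  dates <- sort(unique(layout$date))

  effects <- with_seed(derive_seed(config$seed, "effects"), {
    u <- stats::setNames(stats::rnorm(length(colonies), 0, config$sd_colony),
                         colonies)
    v <- stats::setNames(stats::rnorm(length(dates), 0, config$sd_date),
                         dates)
    g <- stats::setNames(stats::rnorm(length(all_birds), 0,
                                      config$sd_individual), all_birds)
    p <- list()
    for (col in colonies) {
      birds <- sprintf("%s-b%02d", col, seq_len(config$birds_per_colony))
      if (length(birds) >= 2) {
        prs <- utils::combn(birds, 2)
        key <- paste(prs[1, ], prs[2, ], sep = "|")
        p[[col]] <- stats::setNames(
          stats::rnorm(ncol(prs), 0, config$sd_dyad), key)
      }
    }
    list(colony = u, date = v, individual = g, dyad = p)
  })

  eta_cov <- covariate_eta(covs, config$beta)
  names(eta_cov) <- paste(covs$colony_id, covs$date, sep = "|")

  lambda <- with_seed(derive_seed(config$seed, "lambda"), {
    stats::setNames(stats::runif(nrow(layout), config$detection_rate_range[1],
                                 config$detection_rate_range[2]),
                    paste(layout$colony_id, layout$date, sep = "|"))
  })

  perch_cams <- data.frame(camera_id = c("sp1", "sp2", "cp1"),
                           location_type = c("social_perch", "social_perch",
                                             "copulation_perch"),
                           stringsAsFactors = FALSE)

  dyad_prob <- list()
  chunks <- with_seed(derive_seed(config$seed, "detections"), {
    res <- vector("list", nrow(layout))
    for (k in seq_len(nrow(layout))) {
      col <- layout$colony_id[k]; d <- layout$date[k]
      key <- paste(col, d, sep = "|")
      birds <- membership[[key]]
      n <- length(birds)
      if (n < 2) next
      prs <- utils::combn(birds, 2)
      pkey <- paste(prs[1, ], prs[2, ], sep = "|")
      eta <- config$intercept + effects$colony[[col]] + effects$date[[d]] +
        eta_cov[[key]] +
        effects$individual[prs[1, ]] + effects$individual[prs[2, ]] +
        effects$dyad[[col]][pkey]
      p_clump <- stats::plogis(unname(eta))
      dyad_prob[[key]] <- data.frame(colony_id = col, date = d,
                                      bird_a = prs[1, ], bird_b = prs[2, ],
                                      p_clump = p_clump,
                                      stringsAsFactors = FALSE)
      nf <- config$frames_per_day
      ns <- nf * nrow(perch_cams)
      di <- sample.int(ncol(prs), ns, replace = TRUE)
      clump <- stats::rbinom(ns, 1, p_clump[di]) == 1
      thr <- config$clump_threshold_px
      w <- config$perch_width_px
      delta <- integer(ns)
      if (any(clump)) delta[clump] <- sample.int(thr, sum(clump),
                                                 replace = TRUE) - 1L
      if (any(!clump)) delta[!clump] <- thr +
        sample.int(w - thr, sum(!clump), replace = TRUE) - 1L
      x1 <- floor(stats::runif(ns) * (w - delta))
      swap <- stats::runif(ns) < 0.5
      xa <- ifelse(swap, x1 + delta, x1)
      xb <- ifelse(swap, x1, x1 + delta)
      frame <- rep(seq_len(nf), times = nrow(perch_cams))
      cam <- rep(perch_cams$camera_id, each = nf)
      loc <- rep(perch_cams$location_type, each = nf)
      perch <- data.frame(
        colony_id = col, date = d,
        frame_id = c(frame, frame), camera_id = c(cam, cam),
        location_type = c(loc, loc),
        bird_id = c(prs[1, di], prs[2, di]),
        x_px = as.integer(c(xa, xb)),
        stringsAsFactors = FALSE)

      cov_row <- covs[covs$colony_id == col & covs$date == d, ]
      n_tables <- if (cov_row$aviary_area_m2 > 12) 2L else 1L
      eta_f <- config$feeder_intercept + effects$colony[[col]] +
        effects$date[[d]] + eta_cov[[key]] + effects$individual[birds]
      p_join <- stats::plogis(unname(eta_f))
      pres <- matrix(stats::runif(n * nf) < rep(p_join, nf), nrow = n)
      idx <- which(pres, arr.ind = TRUE)
      feeder <- NULL
      if (nrow(idx)) {
        tab <- sample.int(n_tables, nrow(idx), replace = TRUE)
        feeder <- data.frame(
          colony_id = col, date = d,
          frame_id = as.integer(idx[, 2]),
          camera_id = paste0("f", tab),
          location_type = "feeder",
          bird_id = birds[idx[, 1]],
          x_px = NA_integer_,
          stringsAsFactors = FALSE)
      }
      day <- rbind(perch, feeder)
      keep <- stats::runif(nrow(day)) < lambda[[key]]
      res[[k]] <- day[keep, , drop = FALSE]
    }
    res
  })
  detections <- do.call(rbind, chunks)
  rownames(detections) <- NULL

  masked <- data.frame(colony_id = character(), date = character(),
                       stringsAsFactors = FALSE)
  if (config$n_masked_pre_association > 0) {
    pre <- layout[layout$season == "pre", ]
    if (config$n_masked_pre_association > nrow(pre))
      stop_cn("cannot mask %d pre-breeding colony-days; only %d exist",
              config$n_masked_pre_association, nrow(pre))
    pick <- with_seed(derive_seed(config$seed, "masking"),
                      sample.int(nrow(pre), config$n_masked_pre_association))
    masked <- pre[pick, c("colony_id", "date")]
    drop <- detections$location_type == "feeder" &
      paste(detections$colony_id, detections$date) %in%
        paste(masked$colony_id, masked$date)
    detections <- detections[!drop, , drop = FALSE]
    rownames(detections) <- NULL
  }

  ground_truth <- list(
    colony_effects = effects$colony,
    date_effects = effects$date,
    individual_effects = effects$individual,
    dyad_effects = effects$dyad,
    dyad_clump_prob = do.call(rbind, dyad_prob),
    detection_rates = lambda,
    covariate_table = covs,
    membership = membership,
    masked_association_days = masked,
    config = config)
  list(detections = detections, covariates = covs,
       ground_truth = ground_truth)
}
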