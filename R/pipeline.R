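# End-to-end pipeline: simulate (or load) detections -> daily networks ->
# seven metrics -> covariate join -> uninformed / informed models ->
# repeatability, with study accounting and a machine-readable manifest.

PIPELINE_KEYS <- c("detections_csv", "covariates_csv", "synthetic",
                   "threshold_px", "correction_reps", "correction_topology",
                   "bootstrap_reps", "bootstrap_type", "seed", "stages")

#' Default pipeline configuration
#'
#' A fully synthetic run: the generator settings live under `$synthetic`
#' (see [synthetic_config()]); real data can be slotted in by setting
#' `detections_csv` / `covariates_csv` instead. `bootstrap_reps = 0`
#' skips the bootstrap stage.
#'
#' @param ... overrides of top-level keys.
#' @return named list of pipeline settings.
#' @export
pipeline_config <- function(...) {
  cfg <- list(detections_csv = NULL, covariates_csv = NULL,
              synthetic = list(), threshold_px = 80,
              correction_reps = 100, correction_topology = "chain",
              bootstrap_reps = 0, bootstrap_type = "parametric",
              seed = 1L, stages = c("data", "networks", "metrics", "models"))
  over <- list(...)
  bad <- setdiff(names(over), PIPELINE_KEYS)
  if (length(bad))
    stop_cn("unknown pipeline config key(s): %s", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  cfg
}

#' Read a pipeline config from a YAML file
#' @param path YAML file whose keys match [pipeline_config()] (with
#'   `synthetic` keys matching [synthetic_config()]).
#' @return validated config list.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw)
}

#' Study accounting: networks built versus networks expected
#'
#' @param network_index data.frame with columns `colony_id`, `date`,
#'   `net_type`, `season` (one row per built network).
#' @param expected_design data.frame of expected colony-days with columns
#'   `colony_id`, `date`, `season` (each expected to yield one network per
#'   type).
#' @return list `n_networks_total`, `n_networks_pre`, `n_networks_post`,
#'   `n_missing`, and `presence` (expected colony-day-types with a
#'   `present` flag).
#' @export
account_networks <- function(network_index, expected_design) {
  assert_columns(network_index, c("colony_id", "date", "net_type", "season"),
                 "network index")
  assert_columns(expected_design, c("colony_id", "date", "season"),
                 "expected design")
  expected <- merge(expected_design, data.frame(net_type = NET_TYPES),
                    by = NULL)
  key_e <- paste(expected$colony_id, expected$date, expected$net_type)
  key_p <- paste(network_index$colony_id, network_index$date,
                 network_index$net_type)
  expected$present <- key_e %in% key_p
  list(n_networks_total = nrow(network_index),
       n_networks_pre = sum(network_index$season == "pre"),
       n_networks_post = sum(network_index$season == "post"),
       n_missing = sum(!expected$present),
       presence = expected)
}

season_lookup <- function(covs) {
  stats::setNames(covs$season, paste(covs$colony_id, covs$date, sep = "|"))
}

#' Run the full analysis pipeline
#'
#' Stages: `data` (simulate a study, or read detection/covariate CSVs),
#' `networks` (daily interaction + association networks and accounting),
#' `metrics` (seven metrics per network, corrected global metrics),
#' `models` (per metric, network type and season: uninformed and informed
#' fits, repeatability, marginal/conditional R2, optional bootstrap CIs).
#' All outputs are written as CSV/JSON under `outdir`, together with a run
#' manifest recording the seed and every toggle in effect.
#'
#' @param config a [pipeline_config()] (or path to a YAML file).
#' @param outdir output directory (created if needed).
#' @param seed optional override of `config$seed`.
#' @return invisibly, a list with the in-memory results (`detections`,
#'   `covariates`, `networks`, `network_index`, `accounting`, `metrics`,
#'   `model_table`s, `results`).
#' @export
run_pipeline <- function(config = pipeline_config(), outdir = tempfile(),
                         seed = NULL) {
  if (is.character(config)) config <- read_pipeline_config(config)
  config <- do.call(pipeline_config, config)
  if (!is.null(seed)) config$seed <- as.integer(seed)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  stages <- config$stages
  res <- list(config = config)

  ## data
  if (is.null(config$detections_csv)) {
    scfg <- do.call(synthetic_config,
                    utils::modifyList(config$synthetic,
                                      list(seed = config$seed)))
    sim <- simulate_study(scfg)
    res$detections <- sim$detections
    res$covariates <- sim$covariates
    res$ground_truth <- sim$ground_truth
    res$expected_design <- study_layout(scfg)
    write_detections(res$detections, file.path(outdir, "detections.csv"))
  } else {
    res$detections <- read_detections(config$detections_csv)
    res$covariates <- read_covariates(config$covariates_csv)
    if (!"season" %in% names(res$covariates))
      stop_cn("covariates must carry a season column (pre/post)")
    res$expected_design <- unique(
      res$covariates[, c("colony_id", "date", "season")])
  }
  res$covariates <- impute_humidity(res$covariates)
  write_covariates(res$covariates, file.path(outdir, "covariates.csv"))
  res$summaries <- summarize_detections(res$detections)

  if (!"networks" %in% stages) return(finish_pipeline(res, outdir))

  ## networks
  res$networks <- build_study_networks(res$detections, config$threshold_px)
  season_of <- season_lookup(res$covariates)
  res$network_index <- do.call(rbind, lapply(res$networks, function(net)
    data.frame(colony_id = net$colony_id, date = net$date,
               net_type = net$net_type, n_nodes = net$n_nodes,
               season = season_of[[paste(net$colony_id, net$date,
                                         sep = "|")]],
               stringsAsFactors = FALSE)))
  rownames(res$network_index) <- NULL
  res$accounting <- account_networks(res$network_index, res$expected_design)
  utils::write.csv(edge_table(res$networks),
                   file.path(outdir, "network_edges.csv"), row.names = FALSE)
  jsonlite::write_json(
    res$accounting[c("n_networks_total", "n_networks_pre",
                     "n_networks_post", "n_missing")],
    file.path(outdir, "accounting.json"), auto_unbox = TRUE, pretty = TRUE)

  if (!"metrics" %in% stages) return(finish_pipeline(res, outdir))

  ## metrics
  res$metrics <- metric_table(res$networks, n_reps = config$correction_reps,
                              seed = derive_seed(config$seed, "correction"),
                              topology = config$correction_topology)
  res$metrics <- merge(res$metrics,
                       res$network_index[, c("colony_id", "date", "net_type",
                                             "season")],
                       by = c("colony_id", "date", "net_type"), sort = FALSE)
  utils::write.csv(res$metrics, file.path(outdir, "metrics.csv"),
                   row.names = FALSE)

  if (!"models" %in% stages) return(finish_pipeline(res, outdir))

  ## models
  res$results <- fit_study_models(res$metrics, res$covariates,
                                  res$summaries,
                                  bootstrap_reps = config$bootstrap_reps,
                                  bootstrap_type = config$bootstrap_type,
                                  seed = derive_seed(config$seed, "models"))
  utils::write.csv(res$results, file.path(outdir, "model_results.csv"),
                   row.names = FALSE)
  finish_pipeline(res, outdir)
}

finish_pipeline <- function(res, outdir) {
  manifest <- list(
    package_version = as.character(utils::packageVersion("colonynet")),
    r_version = R.version.string,
    seed = res$config$seed,
    threshold_px = res$config$threshold_px,
    correction_reps = res$config$correction_reps,
    correction_topology = res$config$correction_topology,
    bootstrap_reps = res$config$bootstrap_reps,
    bootstrap_type = res$config$bootstrap_type,
    stages = res$config$stages)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  res$outdir <- outdir
  invisible(res)
}

#' Informed-model fixed effects used by the pipeline
#' @return character vector of model-table column names.
#' @export
driver_terms <- function() {
  c("group_size_z", "age_years", "temp_c_z", "humidity_pct_z",
    "cloud_okta_z", "aspect", "aviary_area_m2", "n_detections_z")
}

# Assemble the model table for one (net_type, season) slice: type-matched
# detection counts, scaling within the slice, factor releveling.
slice_model_table <- function(metrics, covariates, summaries, type, season) {
  m <- metrics[metrics$net_type == type & metrics$season == season, ,
               drop = FALSE]
  if (!nrow(m)) return(NULL)
  covs <- covariates[covariates$season == season, , drop = FALSE]
  det_col <- if (type == "interaction") "n_detections_perch"
  else "n_detections_feeder"
  covs <- merge(covs[, setdiff(names(covs), "n_detections")],
                summaries[, c("colony_id", "date", det_col)],
                by = c("colony_id", "date"), all.x = TRUE)
  names(covs)[names(covs) == det_col] <- "n_detections"
  covs$n_detections[is.na(covs$n_detections)] <- 0L
  num <- c("group_size", "temp_c", "humidity_pct", "cloud_okta",
           "n_detections")
  num <- num[vapply(num, function(cl) stats::sd(covs[[cl]]) > 0, logical(1))]
  covs <- scale_numeric(covs, num)
  join_model_table(m, covs)
}

# Fixed effects that are usable in a slice (present, non-constant).
usable_fixed <- function(tab) {
  keep <- character()
  for (term in driver_terms()) {
    if (!term %in% names(tab)) next
    v <- tab[[term]]
    if (length(unique(v[!is.na(v)])) < 2) next
    keep <- c(keep, term)
  }
  keep
}

#' Fit the full battery of variance-partitioning models
#'
#' One uninformed and one informed model per metric, network type and
#' season, mirroring the study's analysis grid. Returns a tidy results
#' table of variance components, repeatability (uninformed and informed),
#' marginal/conditional R2, and bootstrap CIs when `bootstrap_reps > 0`.
#'
#' @param metrics metric table with a `season` column.
#' @param covariates covariate table (humidity imputed).
#' @param summaries per-colony-day detection totals
#'   (see [summarize_detections()]).
#' @param bootstrap_reps bootstrap replicates (0 = skip).
#' @param bootstrap_type passed to [bootstrap_repeatability()].
#' @param seed integer seed.
#' @return data.frame of results, one row per metric x type x season x
#'   model kind.
#' @export
fit_study_models <- function(metrics, covariates, summaries,
                             bootstrap_reps = 0,
                             bootstrap_type = "parametric", seed = 1L) {
  rows <- list()
  for (type in NET_TYPES) for (season in c("pre", "post")) {
    tab <- slice_model_table(metrics, covariates, summaries, type, season)
    if (is.null(tab) || length(unique(tab$colony_id)) < 2) next
    fixed <- usable_fixed(tab)
    for (metric in metric_names()) {
      if (all(is.na(tab[[metric]]))) next
      for (kind in c("uninformed", "informed")) {
        spec <- if (kind == "uninformed") uninformed_spec(metric)
        else informed_spec(metric, fixed)
        row <- tryCatch({
          vd <- fit_lmm(tab, spec)
          r2 <- r2_marginal_conditional(vd)
          out <- data.frame(
            net_type = type, season = season, metric = metric, model = kind,
            n_obs = vd$n_obs, var_colony = vd$var_colony,
            var_date = vd$var_date, var_resid = vd$var_resid,
            var_fixed = vd$var_fixed, R = repeatability(vd),
            r2_marginal = r2$r2_marginal,
            r2_conditional = r2$r2_conditional,
            ci_low = NA_real_, ci_high = NA_real_,
            converged = vd$converged, stringsAsFactors = FALSE)
          if (bootstrap_reps > 0) {
            est <- bootstrap_repeatability(
              tab, spec, B = bootstrap_reps,
              seed = derive_seed(seed, paste(type, season, metric, kind)),
              type = bootstrap_type)
            out$ci_low <- est$ci_low
            out$ci_high <- est$ci_high
          }
          out
        }, error = function(e) {
          data.frame(net_type = type, season = season, metric = metric,
                     model = kind, n_obs = NA_integer_,
                     var_colony = NA_real_, var_date = NA_real_,
                     var_resid = NA_real_, var_fixed = NA_real_,
                     R = NA_real_, r2_marginal = NA_real_,
                     r2_conditional = NA_real_, ci_low = NA_real_,
                     ci_high = NA_real_, converged = FALSE,
                     stringsAsFactors = FALSE)
        })
        rows[[length(rows) + 1]] <- row
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
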