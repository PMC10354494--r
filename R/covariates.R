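# External-driver table assembly: humidity imputation, centring/scaling,
# and the metric-covariate join that feeds the mixed models.

#' Impute missing humidity by year mean
#'
#' Each missing `humidity_pct` is replaced by the mean of the non-missing
#' humidity values from the same calendar year. Observed values are left
#' bit-identical.
#'
#' @param covs covariate rows (needs `date`, `humidity_pct`).
#' @param max_missing_frac error if more than this fraction is missing.
#' @return covariate rows with humidity complete.
#' @export
impute_humidity <- function(covs, max_missing_frac = 0.25) {
  assert_columns(covs, c("date", "humidity_pct"), "covariates table")
  miss <- is.na(covs$humidity_pct)
  if (!any(miss)) return(covs)
  if (mean(miss) > max_missing_frac)
    stop_cn("%.0f%% of humidity values missing (limit %.0f%%)",
            100 * mean(miss), 100 * max_missing_frac)
  year <- substr(covs$date, 1, 4)
  for (y in unique(year[miss])) {
    obs <- covs$humidity_pct[year == y & !miss]
    if (!length(obs))
      stop_cn("all humidity values missing in year %s; cannot impute", y)
    covs$humidity_pct[year == y & miss] <- mean(obs)
  }
  covs
}

#' Centre and scale numeric covariate columns
#'
#' Adds `<col>_z = (x - mean)/sd` for each requested column (sd with the
#' n-1 denominator) and stores the scaling parameters in the `"scaling"`
#' attribute for back-transformation of partial residuals.
#'
#' @param covs covariate rows.
#' @param columns character vector of numeric column names.
#' @return the table with `_z` columns appended.
#' @export
scale_numeric <- function(covs, columns) {
  assert_columns(covs, columns, "covariates table")
  params <- list()
  for (col in columns) {
    x <- covs[[col]]
    if (!is.numeric(x)) stop_cn("column %s is not numeric", col)
    if (anyNA(x)) stop_cn("column %s has missing values; impute first", col)
    s <- stats::sd(x)
    if (!is.finite(s) || s == 0)
      stop_cn("column %s is constant; cannot scale", col)
    covs[[paste0(col, "_z")]] <- (x - mean(x)) / s
    params[[col]] <- c(center = mean(x), scale = s)
  }
  attr(covs, "scaling") <- params
  covs
}

#' Join metric rows to scaled covariates
#'
#' Inner join on (colony_id, date) that must be lossless: every metric row
#' needs exactly one covariate row (unmatched colony-days are an error, not
#' a silent drop). Factor drivers are encoded with documented reference
#' levels: aspect = northeast, aviary area = 12 m2, age = 1 year, so the
#' model contrasts are 0/1 indicators for southwest / 24 m2 / 2 years.
#'
#' @param metrics metric table rows (one colony-day-type subset).
#' @param covs scaled covariate rows.
#' @return the joined model table (factors releveled as documented).
#' @export
join_model_table <- function(metrics, covs) {
  assert_columns(metrics, c("colony_id", "date"), "metrics table")
  assert_columns(covs, c("colony_id", "date"), "covariates table")
  key_m <- paste(metrics$colony_id, metrics$date, sep = "|")
  key_c <- paste(covs$colony_id, covs$date, sep = "|")
  unmatched <- setdiff(key_m, key_c)
  if (length(unmatched))
    stop_cn("no covariate row for colony-day(s): %s",
            paste(utils::head(unmatched, 10), collapse = ", "))
  out <- merge(metrics, covs, by = c("colony_id", "date"), sort = FALSE)
  if (nrow(out) != nrow(metrics))
    stop_cn("join changed the row count (%d -> %d); duplicated covariates?",
            nrow(metrics), nrow(out))
  if ("aspect" %in% names(out))
    out$aspect <- factor(out$aspect, levels = c("northeast", "southwest"))
  if ("aviary_area_m2" %in% names(out))
    out$aviary_area_m2 <- factor(out$aviary_area_m2,
                                 levels = sort(unique(out$aviary_area_m2)))
  if ("age_years" %in% names(out))
    out$age_years <- factor(out$age_years,
                            levels = sort(unique(out$age_years)))
  attr(out, "scaling") <- attr(covs, "scaling")
  attr(out, "reference_levels") <- c(aspect = "northeast",
                                     aviary_area_m2 = "12",
                                     age_years = "1")
  out[order(out$colony_id, out$date), , drop = FALSE]
}
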