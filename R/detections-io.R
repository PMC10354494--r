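# Reading, writing and validating the tabular interchange formats.
#
# Detections CSV columns:
#   colony_id,date,frame_id,camera_id,location_type,bird_id,x_px
# Covariates CSV columns:
#   colony_id,date,group_size,age_years,temp_c,humidity_pct,cloud_okta,
#   aspect,aviary_area_m2,n_detections
# Dates are ISO-8601 strings; frame_id is an integer index within a
# colony-day-camera (the cameras' fixed 3 s cadence is metadata only).

DETECTION_COLS <- c("colony_id", "date", "frame_id", "camera_id",
                    "location_type", "bird_id", "x_px")
COVARIATE_COLS <- c("colony_id", "date", "group_size", "age_years", "temp_c",
                    "humidity_pct", "cloud_okta", "aspect", "aviary_area_m2",
                    "n_detections")

#' Validate a detection-record table
#'
#' Checks the schema, the `location_type` enum, ISO dates, pixel positions
#' (required and non-negative on perch rows) and uniqueness of
#' (colony_id, date, frame_id, camera_id, bird_id). Errors name offending
#' rows by line number (header = line 1).
#'
#' @param records data.frame of detection records.
#' @return the validated data.frame, invisibly usable downstream.
#' @export
validate_detections <- function(records) {
  assert_columns(records, DETECTION_COLS, "detections table")
  records <- records[, DETECTION_COLS]
  if (!nrow(records)) return(records)
  lines <- seq_len(nrow(records)) + 1L
  bad_loc <- !(records$location_type %in% LOCATION_TYPES)
  if (any(bad_loc))
    stop_cn("unknown location_type %s at line(s) %s",
            paste(unique(records$location_type[bad_loc]), collapse = ", "),
            paste(utils::head(lines[bad_loc], 5), collapse = ", "))
  bad_date <- !is_iso_date(records$date)
  if (any(bad_date))
    stop_cn("malformed date at line(s) %s",
            paste(utils::head(lines[bad_date], 5), collapse = ", "))
  perch <- records$location_type %in% PERCH_TYPES
  bad_px <- perch & (is.na(records$x_px) | records$x_px < 0)
  if (any(bad_px))
    stop_cn("perch record without a valid x_px at line(s) %s",
            paste(utils::head(lines[bad_px], 5), collapse = ", "))
  key <- paste(records$colony_id, records$date, records$frame_id,
               records$camera_id, records$bird_id, sep = "\r")
  dup <- duplicated(key)
  if (any(dup))
    stop_cn("duplicate (colony, date, frame, camera, bird) key at line(s) %s",
            paste(utils::head(lines[dup], 5), collapse = ", "))
  records
}

#' Read a detections CSV
#'
#' @param path file path.
#' @return validated data.frame of detection records.
#' @export
read_detections <- function(path) {
  if (!file.exists(path)) stop_cn("file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(colony_id = "character",
                                       date = "character",
                                       frame_id = "integer",
                                       camera_id = "character",
                                       location_type = "character",
                                       bird_id = "character",
                                       x_px = "integer"))
  validate_detections(df)
}

#' Write a detections CSV
#'
#' @param records detection records (validated on the way out).
#' @param path destination path.
#' @export
write_detections <- function(records, path) {
  records <- validate_detections(records)
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}

#' Per-colony-day detection totals
#'
#' One summary row per colony-day present in `records`: perch detections
#' (social + copulation perches), feeder detections, and the number of
#' distinct birds seen. These totals are the "daily camera detections"
#' methodological driver used in the informed models.
#'
#' @param records validated detection records.
#' @return data.frame with columns `colony_id`, `date`,
#'   `n_detections_perch`, `n_detections_feeder`, `n_birds_seen`.
#' @export
summarize_detections <- function(records) {
  records <- validate_detections(records)
  if (!nrow(records))
    return(data.frame(colony_id = character(), date = character(),
                      n_detections_perch = integer(),
                      n_detections_feeder = integer(),
                      n_birds_seen = integer(), stringsAsFactors = FALSE))
  key <- interaction(records$colony_id, records$date, drop = TRUE, sep = "|")
  perch <- as.integer(records$location_type %in% PERCH_TYPES)
  agg <- data.frame(
    key = levels(key),
    n_detections_perch = as.integer(rowsum(perch, key)),
    n_detections_feeder = as.integer(rowsum(1L - perch, key)),
    n_birds_seen = as.integer(tapply(records$bird_id, key,
                                     function(b) length(unique(b)))),
    stringsAsFactors = FALSE)
  parts <- strsplit(agg$key, "|", fixed = TRUE)
  out <- data.frame(colony_id = vapply(parts, `[`, "", 1),
                    date = vapply(parts, `[`, "", 2),
                    agg[, -1, drop = FALSE], stringsAsFactors = FALSE)
  out <- out[order(out$colony_id, out$date), ]
  rownames(out) <- NULL
  out
}

#' Validate a covariate table
#' @param covs data.frame of covariate rows.
#' @return the validated data.frame.
#' @export
validate_covariates <- function(covs) {
  assert_columns(covs, COVARIATE_COLS, "covariates table")
  if (!nrow(covs)) return(covs)
  if (anyDuplicated(paste(covs$colony_id, covs$date)))
    stop_cn("covariates table has duplicated colony-days")
  bad_date <- !is_iso_date(covs$date)
  if (any(bad_date))
    stop_cn("malformed covariate date at row(s) %s",
            paste(utils::head(which(bad_date), 5), collapse = ", "))
  if (any(!covs$cloud_okta %in% 0:8))
    stop_cn("cloud_okta outside 0..8")
  if (any(!covs$aspect %in% c("northeast", "southwest")))
    stop_cn("aspect must be northeast or southwest")
  covs
}

#' Read a covariates CSV
#' @param path file path.
#' @return validated covariate data.frame.
#' @export
read_covariates <- function(path) {
  if (!file.exists(path)) stop_cn("file not found: %s", path)
  validate_covariates(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Write a covariates CSV
#' @param covs covariate rows.
#' @param path destination path.
#' @export
write_covariates <- function(covs, path) {
  covs <- validate_covariates(covs)
  utils::write.csv(covs, path, row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}
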