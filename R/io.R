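# PPG record and feature-table containers and their text-format I/O.
#
# Records travel as a CSV (header `time,<ch>,...`, time in seconds from
# record start) plus a JSON sidecar carrying the sampling rate and metadata.
# Feature tables are plain CSV. Both round-trip at double precision.

VALID_LOCATIONS <- c("forehead", "ear", "finger", "unknown")

#' Construct a multi-channel PPG record
#'
#' @param samples numeric matrix, time points in rows, channels in columns.
#' @param fs sampling frequency in Hz.
#' @param channel_ids character vector of channel names (default `ch_1` ...).
#' @param record_id identifier string.
#' @param location sensor site: one of `"forehead"`, `"ear"`, `"finger"`,
#'   `"unknown"`.
#' @param label optional class label, `"BL"` (blood loss) or `"NBL"`.
#' @param start_time_s offset of the first sample in seconds.
#' @return An object of class `ppg_record`.
#' @export
ppg_record <- function(samples, fs, channel_ids = NULL, record_id = "rec",
                       location = "unknown", label = NULL, start_time_s = 0) {
  samples <- as.matrix(samples)
  if (!is.numeric(samples) || nrow(samples) < 1)
    stopf("samples must be a numeric matrix with >= 1 row")
  if (anyNA(samples) || any(!is.finite(samples)))
    stopf("samples contain missing or non-finite values")
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0)
    stopf("fs must be a single positive number")
  if (is.null(channel_ids)) channel_ids <- paste0("ch_", seq_len(ncol(samples)))
  if (length(channel_ids) != ncol(samples))
    stopf("channel_ids length (%d) != number of channels (%d)",
          length(channel_ids), ncol(samples))
  if (!location %in% VALID_LOCATIONS)
    stopf("location must be one of: %s", paste(VALID_LOCATIONS, collapse = ", "))
  if (!is.null(label) && !label %in% c("BL", "NBL"))
    stopf("label must be \"BL\", \"NBL\" or NULL")
  colnames(samples) <- channel_ids
  structure(list(samples = samples, fs = fs, channel_ids = channel_ids,
                 record_id = record_id, location = location, label = label,
                 start_time_s = start_time_s),
            class = "ppg_record")
}

#' @export
print.ppg_record <- function(x, ...) {
  cat(sprintf("PPG record '%s': %d channels, %d samples @ %g Hz (%.1f s), location %s, label %s\n",
              x$record_id, ncol(x$samples), nrow(x$samples), x$fs,
              nrow(x$samples) / x$fs, x$location,
              if (is.null(x$label)) "<none>" else x$label))
  invisible(x)
}

# duration in seconds
record_duration <- function(record) nrow(record$samples) / record$fs

default_sidecar_path <- function(path) paste0(sub("\\.[^./]+$", "", path), ".json")

#' Write a PPG record as CSV + JSON sidecar
#'
#' @param record a [ppg_record()].
#' @param path CSV output path; the sidecar is written next to it unless
#'   `sidecar_path` is given.
#' @param sidecar_path optional explicit sidecar path.
#' @return Invisibly, the two paths written.
#' @export
write_record <- function(record, path, sidecar_path = NULL) {
  stopifnot(inherits(record, "ppg_record"))
  if (is.null(sidecar_path)) sidecar_path <- default_sidecar_path(path)
  n <- nrow(record$samples)
  tab <- data.frame(time = record$start_time_s + (seq_len(n) - 1) / record$fs,
                    record$samples, check.names = FALSE)
  utils::write.csv(format(tab, digits = 17, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  meta <- list(fs = record$fs, record_id = record$record_id,
               location = record$location,
               label = if (is.null(record$label)) NA else record$label,
               start_time_s = record$start_time_s,
               channel_ids = as.list(record$channel_ids))
  jsonlite::write_json(meta, sidecar_path, auto_unbox = TRUE, digits = NA)
  invisible(c(path, sidecar_path))
}

#' Read a PPG record from CSV + JSON sidecar
#'
#' The time column must be uniformly spaced at the sidecar's sampling rate
#' (within 1e-6 s); any gap, extra jitter or missing value is an error, never
#' imputed.
#'
#' @param path CSV path with header `time,<ch1>,...`.
#' @param sidecar_path JSON sidecar path (default: `path` with `.json`).
#' @return A [ppg_record()].
#' @export
read_record <- function(path, sidecar_path = NULL) {
  if (is.null(sidecar_path)) sidecar_path <- default_sidecar_path(path)
  if (!file.exists(path)) stopf("record file not found: %s", path)
  if (!file.exists(sidecar_path)) stopf("sidecar not found: %s", sidecar_path)
  meta <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  for (k in c("fs", "record_id", "location"))
    if (is.null(meta[[k]])) stopf("sidecar missing key '%s'", k)
  tab <- utils::read.csv(path, check.names = FALSE)
  if (!"time" %in% names(tab)) stopf("record file missing 'time' column")
  if (ncol(tab) < 2) stopf("record file has no channel columns")
  if (anyNA(tab)) {
    bad <- which(apply(is.na(tab), 1, any))[1]
    stopf("missing value in record at row %d", bad)
  }
  tt <- tab$time
  fs <- meta$fs
  expected <- tt[1] + (seq_along(tt) - 1) / fs
  dev <- abs(tt - expected)
  if (any(dev > 1e-6))
    stopf("non-uniform or rate-inconsistent time base at row %d (expected step %g s)",
          which(dev > 1e-6)[1], 1 / fs)
  label <- meta$label
  if (is.null(label) || (length(label) == 1 && is.na(label))) label <- NULL
  ppg_record(as.matrix(tab[, -1, drop = FALSE]), fs = fs,
             channel_ids = names(tab)[-1], record_id = meta$record_id,
             location = meta$location, label = label, start_time_s = tt[1])
}

FEATURE_COLS <- c("record_id", "label", "r2", "slope", "pct_change", "abs_change")

validate_features <- function(tab) {
  missing <- setdiff(FEATURE_COLS, names(tab))
  if (length(missing))
    stopf("feature table missing column(s): %s", paste(missing, collapse = ", "))
  tab <- tab[, FEATURE_COLS]
  if (anyDuplicated(tab$record_id))
    stopf("duplicate record_id in feature table: %s",
          tab$record_id[anyDuplicated(tab$record_id)])
  num <- c("r2", "slope", "pct_change", "abs_change")
  if (nrow(tab) > 0) {
    if (anyNA(tab) || any(!is.finite(as.matrix(tab[, num]))))
      stopf("feature table contains missing or non-finite values")
    if (any(tab$r2 < 0 | tab$r2 > 1)) stopf("r2 out of [0, 1]")
    if (!all(tab$label %in% c("BL", "NBL")))
      stopf("label must be BL or NBL")
  }
  tab
}

#' Write / read a feature table (CSV)
#'
#' Columns: `record_id, label, r2, slope, pct_change, abs_change`.
#' Round-trips losslessly at double precision; duplicate `record_id` is an
#' error on read and on write.
#'
#' @param features data.frame with the six feature-table columns.
#' @param path CSV path.
#' @return `write_features`: the path, invisibly. `read_features`: the table.
#' @export
write_features <- function(features, path) {
  tab <- validate_features(as.data.frame(features))
  out <- tab
  for (k in c("r2", "slope", "pct_change", "abs_change"))
    out[[k]] <- sprintf("%.17g", tab[[k]])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  if (!file.exists(path)) stopf("feature file not found: %s", path)
  tab <- utils::read.csv(path, colClasses = c(record_id = "character",
                                              label = "character"))
  validate_features(tab)
}
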