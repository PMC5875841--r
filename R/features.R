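# From one PPG recording to the 4-feature trend vector.
#
# Scheme: 2-minute sequences are taken along the recording; within each
# sequence a 1-minute window slides in 10-second steps (7 windows). Each
# window yields a VFCDM spectrum whose heart-rate-band maximum, averaged
# over interior time samples, gives one amplitude estimate; the 7 window
# estimates average to the sequence's mean AM_HR. The AM_HR-versus-time
# series is then summarized by an ordinary least-squares trend line:
# r-squared, slope, and the percentage and signed change between the first
# and last points. Positive slope/changes indicate euvolemia, negative
# ones blood loss.

#' Sequence/window scheme
#'
#' @param seq_len_s sequence length in seconds (default 120).
#' @param win_len_s sliding-window length in seconds (default 60).
#' @param shift_s window shift in seconds (default 10); with the defaults
#'   each sequence holds 7 windows.
#' @param starts optional explicit sequence start times in seconds; default
#'   is consecutive non-overlapping `seq_len_s` blocks.
#' @return An object of class `window_scheme`.
#' @export
window_scheme <- function(seq_len_s = 120, win_len_s = 60, shift_s = 10,
                          starts = NULL) {
  if (win_len_s >= seq_len_s) stopf("win_len_s must be < seq_len_s")
  if ((seq_len_s - win_len_s) %% shift_s != 0)
    stopf("(seq_len_s - win_len_s) must be divisible by shift_s")
  structure(list(seq_len_s = seq_len_s, win_len_s = win_len_s,
                 shift_s = shift_s, starts = starts),
            class = "window_scheme")
}

#' Heart-rate frequency band
#'
#' Defaults 0.66-3.0 Hz (40-180 bpm): wide enough for trauma-relevant heart
#' rates, and bounded below well above the respiratory band (< 0.5 Hz).
#'
#' @param f_lo,f_hi band limits in Hz.
#' @return An object of class `hr_band`.
#' @export
hr_band <- function(f_lo = 0.66, f_hi = 3.0) {
  if (f_lo < 0.5) stopf("f_lo must be >= 0.5 Hz to exclude the respiratory band")
  if (f_hi <= f_lo) stopf("f_hi must exceed f_lo")
  structure(list(f_lo = f_lo, f_hi = f_hi), class = "hr_band")
}

#' Extract the analysis sequences from a record
#'
#' Returns the selected channel's samples for each sequence block; partial
#' trailing blocks are dropped. A recording must hold at least two
#' sequences for a trend to exist.
#'
#' @param record a [ppg_record()].
#' @param scheme a [window_scheme()].
#' @param channel channel index to extract; default: minimum-entropy
#'   channel via [select_channel()].
#' @return List of lists with `start_s` and `samples`.
#' @export
extract_sequences <- function(record, scheme = window_scheme(),
                              channel = NULL) {
  stopifnot(inherits(record, "ppg_record"))
  dur <- record_duration(record)
  if (dur < 2 * scheme$seq_len_s)
    stopf("recording too short for trend analysis: %.1f s < %g s",
          dur, 2 * scheme$seq_len_s)
  if (is.null(channel)) channel <- select_channel(record)$index
  starts <- scheme$starts
  if (is.null(starts))
    starts <- seq(0, dur - scheme$seq_len_s, by = scheme$seq_len_s)
  starts <- starts[starts + scheme$seq_len_s <= dur + 1e-9]
  if (length(starts) < 2)
    stopf("recording too short for trend analysis: fewer than 2 sequences")
  x <- record$samples[, channel]
  lapply(starts, function(s0) {
    i0 <- round(s0 * record$fs) + 1
    list(start_s = s0,
         samples = x[i0:(i0 + round(scheme$seq_len_s * record$fs) - 1)])
  })
}

#' Mean heart-rate-band amplitude of one sequence
#'
#' Decimates the sequence to the analysis rate, slides the 1-minute window
#' in 10-second steps, computes the VFCDM spectrum of each window, averages
#' the heart-rate-band maximum over the window's interior time samples, and
#' averages the per-window values.
#'
#' @param x numeric samples of one sequence at the native rate.
#' @param fs native sampling rate in Hz.
#' @param band a [hr_band()].
#' @param scheme a [window_scheme()] (window length and shift).
#' @param config a [vfcdm_config()].
#' @return The sequence's mean AM_HR (scalar, signal units).
#' @export
amhr_from_sequence <- function(x, fs, band = hr_band(),
                               scheme = window_scheme(),
                               config = vfcdm_config()) {
  if (band$f_hi > config$f_max)
    stopf("band upper limit %g Hz exceeds analysis Nyquist %g Hz",
          band$f_hi, config$f_max)
  xd <- decimate_ppg(x, fs, config$fs_d)
  offsets <- seq(0, scheme$seq_len_s - scheme$win_len_s, by = scheme$shift_s)
  nw <- round(scheme$win_len_s * config$fs_d)
  vals <- vapply(offsets, function(o) {
    i0 <- round(o * config$fs_d) + 1
    tfs <- vfcdm_tfs(xd[i0:(i0 + nw - 1)], config$fs_d, config)
    mean(tfs_band_max(tfs, band$f_lo, band$f_hi))
  }, numeric(1))
  mean(vals)
}

#' AM_HR series container
#'
#' @param times sequence-center times in seconds, strictly increasing.
#' @param values mean AM_HR per sequence, all >= 0.
#' @return An object of class `amhr_series`.
#' @export
amhr_series <- function(times, values) {
  if (length(times) != length(values) || length(times) < 2)
    stopf("amhr_series needs >= 2 (time, value) pairs")
  if (any(diff(times) <= 0)) stopf("times must be strictly increasing")
  if (any(values < 0)) stopf("AM_HR values must be >= 0")
  structure(list(times = times, values = values), class = "amhr_series")
}

#' @export
print.amhr_series <- function(x, ...) {
  cat(sprintf("AM_HR series: %d points over %.1f s, mean %.4g\n",
              length(x$times), diff(range(x$times)), mean(x$values)))
  invisible(x)
}

#' @export
plot.amhr_series <- function(x, ...) {
  graphics::plot(x$times, x$values, type = "b", col = "blue",
                 xlab = "Time (s)", ylab = "mean AM_HR", ...)
  graphics::abline(stats::lm(x$values ~ x$times), col = "red")
  invisible(x)
}

#' Trend features of an AM_HR series
#'
#' Ordinary least-squares line of AM_HR versus time: reports the slope
#' (signal units per second) and r-squared (`1 - SS_res/SS_tot`), plus the
#' signed change `value_last - value_first` and the percentage change
#' `100 * signed change / value_first`. A constant series carries no trend
#' evidence: `SS_tot = 0` yields r-squared 0 (and zero slope/changes). A
#' first value of 0 makes the percentage change undefined and is an error.
#'
#' @param series an [amhr_series()].
#' @return A named list of class `ppg_features`: `r2`, `slope`,
#'   `pct_change`, `abs_change`.
#' @export
trend_features <- function(series) {
  stopifnot(inherits(series, "amhr_series"))
  t <- series$times
  v <- series$values
  if (v[1] == 0) stopf("first AM_HR value is 0: percentage change undefined")
  ss_tot <- sum((v - mean(v))^2)
  if (ss_tot == 0) {
    out <- list(r2 = 0, slope = 0, pct_change = 0, abs_change = 0)
  } else {
    slope <- sum((t - mean(t)) * (v - mean(v))) / sum((t - mean(t))^2)
    fit <- mean(v) + slope * (t - mean(t))
    r2 <- 1 - sum((v - fit)^2) / ss_tot
    abs_change <- v[length(v)] - v[1]
    out <- list(r2 = r2, slope = slope,
                pct_change = 100 * abs_change / v[1], abs_change = abs_change)
  }
  structure(out, class = "ppg_features")
}

#' @export
print.ppg_features <- function(x, ...) {
  cat(sprintf("trend features: r2 = %.4f, slope = %.3e /s, pct_change = %.2f%%, abs_change = %.4g\n",
              x$r2, x$slope, x$pct_change, x$abs_change))
  invisible(x)
}

#' Full per-record feature extraction
#'
#' Minimum-entropy channel selection, sequence extraction, per-sequence
#' mean AM_HR, and trend analysis. The AM_HR series and channel audit are
#' returned alongside the features.
#'
#' @param record a [ppg_record()].
#' @param scheme a [window_scheme()].
#' @param band a [hr_band()].
#' @param config a [vfcdm_config()].
#' @param n_bins entropy histogram bins for channel selection.
#' @return A list: `features` ([trend_features()] output), `series`
#'   ([amhr_series()]), `channel` (selected index), `entropies`.
#' @export
featurize_record <- function(record, scheme = window_scheme(),
                             band = hr_band(), config = vfcdm_config(),
                             n_bins = 50) {
  sel <- select_channel(record, n_bins = n_bins)
  seqs <- extract_sequences(record, scheme, channel = sel$index)
  times <- vapply(seqs, function(s) s$start_s + scheme$seq_len_s / 2, numeric(1))
  values <- vapply(seqs, function(s)
    amhr_from_sequence(s$samples, record$fs, band, scheme, config), numeric(1))
  series <- amhr_series(times, values)
  list(features = trend_features(series), series = series,
       channel = sel$index, entropies = sel$entropies)
}

#' Featurize a whole cohort into a feature table
#'
#' @param cohort a `ppg_cohort` (see [simulate_cohort()]).
#' @param ... passed to [featurize_record()].
#' @return A feature table data.frame with columns
#'   `record_id, label, r2, slope, pct_change, abs_change`.
#' @export
featurize_cohort <- function(cohort, ...) {
  stopifnot(inherits(cohort, "ppg_cohort"))
  rows <- lapply(cohort$records, function(rec) {
    f <- featurize_record(rec, ...)$features
    data.frame(record_id = rec$record_id, label = rec$label, r2 = f$r2,
               slope = f$slope, pct_change = f$pct_change,
               abs_change = f$abs_change)
  })
  validate_features(do.call(rbind, rows))
}

#' Truncate a record to its leading portion
#'
#' Supports early-detection analyses on the initial part of a recording
#' (e.g. the portion corresponding to moderate blood withdrawal). If the
#' record is already shorter than requested it is returned unchanged with
#' attribute `truncation_noop = TRUE` and a warning.
#'
#' @param record a [ppg_record()].
#' @param max_duration_s target duration in seconds (>= 240, the minimum
#'   for trend analysis).
#' @return A [ppg_record()] with attribute `truncated_to_s` when shortened.
#' @export
truncate_record <- function(record, max_duration_s) {
  stopifnot(inherits(record, "ppg_record"))
  if (max_duration_s < 240)
    stopf("max_duration_s must be >= 240 s (minimum for trend analysis)")
  dur <- record_duration(record)
  if (max_duration_s >= dur) {
    warning(sprintf("record '%s' is only %.1f s; truncation to %g s is a no-op",
                    record$record_id, dur, max_duration_s))
    attr(record, "truncation_noop") <- TRUE
    return(record)
  }
  n_keep <- round(max_duration_s * record$fs)
  out <- ppg_record(record$samples[seq_len(n_keep), , drop = FALSE],
                    fs = record$fs, channel_ids = record$channel_ids,
                    record_id = record$record_id, location = record$location,
                    label = record$label, start_time_s = record$start_time_s)
  attr(out, "truncated_to_s") <- max_duration_s
  out
}
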