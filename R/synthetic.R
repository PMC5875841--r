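# Seeded synthetic PPG generator.
#
# Emulates the statistical structure the downstream method relies on: a
# pulsatile component at the heart-rate fundamental with decaying-weight
# harmonics, respiratory amplitude modulation plus an additive respiratory
# baseline component below 0.5 Hz, slow baseline wander, per-channel
# additive Gaussian noise (to exercise entropy-based channel selection),
# and an optional linear decay of the heart-rate-band amplitude across the
# recording, the signature of progressive blood loss.

#' Configuration for one synthetic PPG record
#'
#' The heart-rate-band envelope decays linearly from `hr_amp0` at the start
#' to `hr_amp0 * (1 - amp_decay_frac)` at the end of the recording;
#' `amp_decay_frac = 0` is a stationary (euvolemic) record, positive values
#' emulate blood loss, small negative values emulate upward drift.
#'
#' @param duration_s recording length in seconds.
#' @param fs sampling frequency in Hz (default 80).
#' @param hr_hz heart-rate fundamental in Hz.
#' @param hr_amp0 initial heart-rate-band amplitude (arbitrary PPG units).
#' @param amp_decay_frac fractional envelope change start-to-end, in [-1, 1].
#' @param resp_hz respiratory frequency in Hz (must be < 0.5).
#' @param resp_mod_frac fractional respiratory amplitude modulation depth.
#' @param n_harmonics number of harmonics above the fundamental; harmonic
#'   `k` (0 = fundamental) has weight `1/(k+1)` and phase `-k*pi/2`, so all
#'   harmonics peak together (a sharp, PPG-like systolic peak).
#' @param channel_noise_sd per-channel additive Gaussian noise SDs; its
#'   length sets the number of channels.
#' @param wander_amp,wander_hz baseline wander amplitude and frequency.
#' @param seed integer RNG seed for the channel noise.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(duration_s = 600, fs = 80, hr_hz = 1.2, hr_amp0 = 1,
                       amp_decay_frac = 0, resp_hz = 0.3, resp_mod_frac = 0.2,
                       n_harmonics = 2,
                       channel_noise_sd = c(0.05, 0.15, 0.3),
                       wander_amp = 0.3, wander_hz = 0.05, seed = 1) {
  cfg <- list(duration_s = duration_s, fs = fs, hr_hz = hr_hz,
              hr_amp0 = hr_amp0, amp_decay_frac = amp_decay_frac,
              resp_hz = resp_hz, resp_mod_frac = resp_mod_frac,
              n_harmonics = as.integer(n_harmonics),
              channel_noise_sd = channel_noise_sd,
              wander_amp = wander_amp, wander_hz = wander_hz,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  if (cfg$duration_s <= 0) stopf("invalid config: duration_s must be > 0")
  if (cfg$fs <= 2 * cfg$hr_hz * (cfg$n_harmonics + 1))
    stopf("invalid config: fs (%g) must exceed 2*hr_hz*(n_harmonics+1) = %g",
          cfg$fs, 2 * cfg$hr_hz * (cfg$n_harmonics + 1))
  if (cfg$amp_decay_frac < -1 || cfg$amp_decay_frac > 1)
    stopf("invalid config: amp_decay_frac must lie in [-1, 1]")
  if (cfg$resp_hz >= 0.5)
    stopf("invalid config: resp_hz (%g) must be < 0.5 Hz", cfg$resp_hz)
  n <- cfg$duration_s * cfg$fs
  if (abs(n - round(n)) > 1e-9)
    stopf("invalid config: duration_s * fs (%g) must be an integer sample count", n)
  if (length(cfg$channel_noise_sd) < 1 || any(cfg$channel_noise_sd < 0))
    stopf("invalid config: channel_noise_sd must be >= 0, length >= 1")
  if (cfg$n_harmonics < 0) stopf("invalid config: n_harmonics must be >= 0")
  invisible(cfg)
}

#' Simulate one multi-channel PPG record
#'
#' Each channel is `a(t) * (1 + m*sin(2*pi*f_r*t)) * sum_k sin(2*pi*(k+1)*f_h*t)/(k+1)`
#' plus an additive respiratory baseline component at `f_r`, sinusoidal
#' baseline wander, and channel-specific white Gaussian noise, where the
#' envelope `a(t)` decays linearly from `hr_amp0` to
#' `hr_amp0 * (1 - amp_decay_frac)`. Identical seeds give bit-identical
#' records.
#'
#' @param config a [sim_config()].
#' @param record_id identifier for the generated record.
#' @param label optional class label attached to the record.
#' @param location sensor site stored in the metadata.
#' @return A [ppg_record()] with `length(channel_noise_sd)` channels.
#' @export
simulate_record <- function(config, record_id = "sim", label = NULL,
                            location = "unknown") {
  validate_sim_config(config)
  n <- round(config$duration_s * config$fs)
  t <- (seq_len(n) - 1) / config$fs
  a <- config$hr_amp0 * (1 - config$amp_decay_frac * t / config$duration_s)
  # harmonic k has weight 1/(k+1) and phase -k*pi/2, which aligns all
  # harmonic maxima with the fundamental's peak: the resulting waveform has
  # the sharp systolic peak of a real PPG pulse (and hence the concentrated
  # amplitude histogram that minimum-entropy channel selection relies on)
  k <- 0:config$n_harmonics
  pulse <- rowSums(sapply(k, function(kk)
    sin(2 * pi * (kk + 1) * config$hr_hz * t - kk * pi / 2) / (kk + 1)))
  resp_gain <- 1 + config$resp_mod_frac * sin(2 * pi * config$resp_hz * t)
  resp_base <- config$resp_mod_frac * config$hr_amp0 *
    sin(2 * pi * config$resp_hz * t)
  wander <- config$wander_amp * sin(2 * pi * config$wander_hz * t)
  clean <- a * resp_gain * pulse + resp_base + wander
  n_ch <- length(config$channel_noise_sd)
  samples <- with_seed(config$seed, {
    vapply(seq_len(n_ch), function(c_i)
      clean + stats::rnorm(n, 0, config$channel_noise_sd[c_i]), numeric(n))
  })
  rec <- ppg_record(samples, fs = config$fs, record_id = record_id,
                    location = location, label = label)
  attr(rec, "sim_config") <- config
  rec
}

#' Specification of a synthetic labeled cohort
#'
#' Per-record parameters are drawn uniformly from class-specific ranges.
#' The blood-loss (BL) class draws the envelope decay from a strictly
#' positive range; the no-blood-loss (NBL) class from a small range around
#' zero covering mild drifts of either sign. The default sizes reproduce
#' the 65 NBL / 29 BL imbalance of the clinical cohort the method was
#' evaluated on.
#'
#' @param n_bl,n_nbl class sizes (both >= 1).
#' @param duration_s recording length in seconds, common to all records.
#' @param bl_decay_range,nbl_decay_range uniform ranges for
#'   `amp_decay_frac` per class.
#' @param hr_range,resp_range uniform ranges for the heart-rate and
#'   respiratory frequencies (Hz), shared by both classes.
#' @param channel_noise_sd per-channel noise SDs, as in [sim_config()].
#' @param seed master seed; record `i` uses seed `seed + i`, so cohorts are
#'   portable across platforms.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_bl = 29, n_nbl = 65, duration_s = 600,
                        bl_decay_range = c(0.3, 0.6),
                        nbl_decay_range = c(-0.05, 0.05),
                        hr_range = c(0.9, 1.8), resp_range = c(0.15, 0.4),
                        channel_noise_sd = c(0.05, 0.15, 0.3), seed = 1) {
  if (n_bl < 1 || n_nbl < 1)
    stopf("invalid cohort spec: n_bl and n_nbl must both be >= 1")
  if (bl_decay_range[1] <= 0)
    stopf("invalid cohort spec: bl_decay_range must be strictly positive")
  structure(list(n_bl = as.integer(n_bl), n_nbl = as.integer(n_nbl),
                 duration_s = duration_s, bl_decay_range = bl_decay_range,
                 nbl_decay_range = nbl_decay_range, hr_range = hr_range,
                 resp_range = resp_range, channel_noise_sd = channel_noise_sd,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Simulate a labeled cohort of PPG records
#'
#' @param spec a [cohort_spec()].
#' @return An object of class `ppg_cohort`: a list with `records` (list of
#'   [ppg_record()]), `labels`, and a `manifest` data.frame (record_id,
#'   label, seed, and the drawn per-record parameters).
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n_total <- spec$n_bl + spec$n_nbl
  labels <- rep(c("BL", "NBL"), c(spec$n_bl, spec$n_nbl))
  records <- vector("list", n_total)
  manifest <- data.frame(record_id = sprintf("sim_%03d", seq_len(n_total)),
                         label = labels, seed = spec$seed + seq_len(n_total),
                         hr_hz = NA_real_, resp_hz = NA_real_,
                         amp_decay_frac = NA_real_,
                         duration_s = spec$duration_s)
  for (i in seq_len(n_total)) {
    rng <- if (labels[i] == "BL") spec$bl_decay_range else spec$nbl_decay_range
    s_i <- spec$seed + i
    pars <- with_seed(s_i, c(stats::runif(1, spec$hr_range[1], spec$hr_range[2]),
                             stats::runif(1, spec$resp_range[1], spec$resp_range[2]),
                             stats::runif(1, rng[1], rng[2])))
    cfg <- sim_config(duration_s = spec$duration_s, hr_hz = pars[1],
                      resp_hz = pars[2], amp_decay_frac = pars[3],
                      channel_noise_sd = spec$channel_noise_sd, seed = s_i)
    records[[i]] <- simulate_record(cfg, record_id = manifest$record_id[i],
                                    label = labels[i])
    manifest[i, c("hr_hz", "resp_hz", "amp_decay_frac")] <- pars
  }
  structure(list(records = records, labels = labels, manifest = manifest,
                 spec = spec),
            class = "ppg_cohort")
}

#' @export
print.ppg_cohort <- function(x, ...) {
  cat(sprintf("Synthetic PPG cohort: %d records (%d BL, %d NBL), %g s each, master seed %d\n",
              length(x$records), sum(x$labels == "BL"), sum(x$labels == "NBL"),
              x$spec$duration_s, x$spec$seed))
  invisible(x)
}

#' Write a cohort to a directory
#'
#' One CSV + JSON sidecar per record plus a `manifest.csv` with per-record
#' labels, seeds and generator parameters.
#'
#' @param cohort a `ppg_cohort`.
#' @param dir output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "ppg_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (rec in cohort$records)
    write_record(rec, file.path(dir, paste0(rec$record_id, ".csv")))
  utils::write.csv(cohort$manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir directory containing `manifest.csv` and the record files.
#' @return A `ppg_cohort` (without the generator spec).
#' @export
read_cohort <- function(dir) {
  mpath <- file.path(dir, "manifest.csv")
  if (!file.exists(mpath)) stopf("no manifest.csv in %s", dir)
  manifest <- utils::read.csv(mpath, colClasses = c(record_id = "character",
                                                    label = "character"))
  records <- lapply(manifest$record_id, function(id)
    read_record(file.path(dir, paste0(id, ".csv"))))
  structure(list(records = records, labels = manifest$label,
                 manifest = manifest,
                 spec = list(duration_s = manifest$duration_s[1],
                             seed = NA_integer_)),
            class = "ppg_cohort")
}
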