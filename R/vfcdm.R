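# Variable-frequency complex demodulation (VFCDM).
#
# Two-stage time-frequency estimation. Stage 1 (fixed CDM): demodulate the
# signal at fixed center frequencies spaced Fw apart, low-pass at Fw, and
# read off each band's instantaneous amplitude, phase and frequency.
# Stage 2: re-demodulate the signal along each band's time-varying
# instantaneous-frequency trajectory and low-pass at the narrower Fv, which
# centers the analysis on the signal's own frequency and yields
# high-resolution amplitude/frequency estimates that are deposited onto a
# time-frequency grid.
#
# All filters are linear-phase FIR applied with explicit group-delay
# compensation (exact zero phase); signal edges within half a filter length
# are transient and flagged via the spectrum's `edge_s` so downstream
# statistics can exclude them.

#' VFCDM configuration
#'
#' @param fs_d analysis sampling rate in Hz (the input is decimated from the
#'   native rate to this before demodulation; default 20).
#' @param Fw stage-1 band spacing and low-pass cutoff in Hz (default 0.5).
#'   Must divide `f_max` evenly.
#' @param Fv stage-2 low-pass cutoff in Hz (default 0.15); `0 < Fv < Fw`.
#' @param filter_len FIR length in taps, shared by both stages
#'   (default `4 * fs_d / Fw` rounded up to odd).
#' @param f_max top analysis frequency in Hz (default `fs_d / 2`).
#' @param grid_df frequency-grid spacing of the assembled spectrum in Hz
#'   (default 0.1; must be `<= Fv`).
#' @return An object of class `vfcdm_config`.
#' @export
vfcdm_config <- function(fs_d = 20, Fw = 0.5, Fv = 0.15, filter_len = NULL,
                         f_max = fs_d / 2, grid_df = 0.1) {
  if (is.null(filter_len)) filter_len <- round_odd(4 * fs_d / Fw)
  if (Fv <= 0 || Fv >= Fw) stopf("require 0 < Fv < Fw (got Fv=%g, Fw=%g)", Fv, Fw)
  if (abs(f_max / Fw - round(f_max / Fw)) > 1e-9)
    stopf("Fw (%g) must divide f_max (%g) into an integer number of bands", Fw, f_max)
  if (filter_len %% 2 == 0) stopf("filter_len must be odd")
  if (f_max > fs_d / 2 + 1e-12) stopf("f_max cannot exceed fs_d/2")
  if (grid_df > Fv) stopf("grid_df (%g) must be <= Fv (%g)", grid_df, Fv)
  structure(list(fs_d = fs_d, Fw = Fw, Fv = Fv,
                 filter_len = as.integer(filter_len), f_max = f_max,
                 grid_df = grid_df),
            class = "vfcdm_config")
}

# Unit-DC-gain linear-phase FIR low-pass (Hamming window design).
fir_lowpass <- function(n_taps, cutoff_hz, fs) {
  h <- signal::fir1(n_taps - 1, cutoff_hz / (fs / 2))
  h / sum(h)
}

# Zero-phase filtering of a real or complex signal by an odd-length
# linear-phase FIR: reflect-pad by half the filter length, FFT-convolve,
# compensate the group delay, strip the pads. Exact zero phase, gain |H(f)|.
zerophase_filter <- function(x, h) {
  m <- (length(h) - 1) / 2
  n <- length(x)
  pad_l <- x[pmin(m + 1 - seq_len(m) + 1, n)]   # reflect about first sample
  pad_r <- x[pmax(n - seq_len(m), 1)]           # reflect about last sample
  xp <- c(pad_l, x, pad_r)
  N <- stats::nextn(length(xp) + length(h) - 1, 2)
  X <- stats::fft(c(xp, rep(0, N - length(xp))))
  H <- stats::fft(c(h, rep(0, N - length(h))))
  y <- stats::fft(X * H, inverse = TRUE) / N
  # centered output at padded position i is linear-conv index i + m;
  # original samples sit at padded positions (m+1):(m+n)
  out <- y[(2 * m + 1):(2 * m + n)]
  if (is.complex(x)) out else Re(out)
}

#' Decimate a signal to the VFCDM analysis rate
#'
#' Zero-phase FIR anti-alias low-pass at `0.45 * fs_d` followed by
#' subsampling. The native rate must be an integer multiple of `fs_d`.
#'
#' @param x numeric sample vector at `fs_native`.
#' @param fs_native native sampling rate in Hz.
#' @param fs_d target rate in Hz.
#' @param aa_taps anti-alias filter length (default: 5 s of native samples,
#'   rounded to odd).
#' @return Numeric vector sampled at `fs_d`.
#' @export
decimate_ppg <- function(x, fs_native, fs_d, aa_taps = NULL) {
  ratio <- fs_native / fs_d
  if (abs(ratio - round(ratio)) > 1e-9)
    stopf("fs_native (%g) must be an integer multiple of fs_d (%g)", fs_native, fs_d)
  ratio <- round(ratio)
  if (ratio == 1) return(x)
  if (is.null(aa_taps)) aa_taps <- round_odd(5 * fs_native)
  h <- fir_lowpass(aa_taps, 0.45 * fs_d, fs_native)
  y <- zerophase_filter(x, h)
  y[seq(1, length(y), by = ratio)]
}

new_band_component <- function(center_hz, amp, freq, phase) {
  structure(list(center_hz = center_hz, inst_amplitude = amp,
                 inst_frequency = freq, inst_phase = phase),
            class = "cdm_band")
}

#' Stage-1 fixed-frequency complex demodulation
#'
#' For each center frequency `f_c` in `Fw, 2*Fw, ..., f_max - Fw`, the
#' signal is multiplied by `exp(-i*2*pi*f_c*t)` and low-pass filtered at
#' `Fw` (zero-phase FIR). Each band reports instantaneous amplitude
#' `2*|z|`, total instantaneous phase (carrier plus unwrapped low-pass
#' phase, so that `amplitude * cos(phase)` is the band's real signal), and
#' instantaneous frequency `f_c + (1/2pi) * dphi/dt` (central differences).
#'
#' @param x numeric signal at `fs_d`.
#' @param fs_d sampling rate in Hz.
#' @param config a [vfcdm_config()].
#' @return List of `cdm_band` components.
#' @export
fixed_cdm <- function(x, fs_d, config = vfcdm_config(fs_d = fs_d)) {
  if (length(x) <= config$filter_len)
    stopf("signal too short for fixed CDM: need > %d samples, got %d",
          config$filter_len, length(x))
  n <- length(x)
  dt <- 1 / fs_d
  t <- (seq_len(n) - 1) * dt
  h <- fir_lowpass(config$filter_len, config$Fw, fs_d)
  centers <- seq(config$Fw, config$f_max - config$Fw, by = config$Fw)
  lapply(centers, function(fc) {
    z <- zerophase_filter(x * exp(-2i * pi * fc * t), h)
    amp <- 2 * Mod(z)
    phi <- unwrap_phase(Arg(z))
    freq <- fc + num_gradient(phi, dt) / (2 * pi)
    # a band only ever carries content within +/- Fw of its center; outside
    # that the phase derivative is leakage-driven noise, so clamp (this also
    # keeps empty bands from chasing remote components in stage 2)
    freq <- pmin(pmax(freq, fc - config$Fw), fc + config$Fw)
    new_band_component(fc, amp, freq, 2 * pi * fc * t + phi)
  })
}

#' Reconstruct a signal from stage-1 CDM components
#'
#' `0.5 * sum_k amplitude_k * cos(phase_k)`; the factor 1/2 compensates the
#' two-fold overlap of adjacent bands (spacing Fw, cutoff Fw).
#'
#' @param components list of `cdm_band` from [fixed_cdm()].
#' @return Numeric vector.
#' @export
cdm_reconstruct <- function(components) {
  0.5 * Reduce(`+`, lapply(components, function(b)
    b$inst_amplitude * cos(b$inst_phase)))
}

#' VFCDM time-frequency spectrum
#'
#' Runs [fixed_cdm()], then for each stage-1 component re-demodulates the
#' signal along the component's instantaneous-frequency trajectory
#' (`exp(-i * 2*pi * integral of f(tau) dtau)`, cumulative trapezoidal
#' phase), low-passes at the narrower `Fv`, and recomputes refined
#' instantaneous amplitude and frequency. Refined amplitudes are deposited
#' at the nearest frequency-grid bin of their refined instantaneous
#' frequency; collisions keep the maximum.
#'
#' @inheritParams fixed_cdm
#' @return An object of class `ppg_tfs`: `times` (s), `freqs` (Hz),
#'   `amplitude` (times x freqs, >= 0), `fs_d`, and `edge_s`, the duration
#'   at each end still inside the cascaded filters' transients.
#' @export
vfcdm_tfs <- function(x, fs_d, config = vfcdm_config(fs_d = fs_d)) {
  stage1 <- fixed_cdm(x, fs_d, config)
  n <- length(x)
  dt <- 1 / fs_d
  t <- (seq_len(n) - 1) * dt
  h2 <- fir_lowpass(config$filter_len, config$Fv, fs_d)
  freqs <- seq(0, config$f_max, by = config$grid_df)
  amp_grid <- matrix(0, nrow = n, ncol = length(freqs))
  rows <- seq_len(n)
  for (band in stage1) {
    phi_c <- 2 * pi * cum_trapz(band$inst_frequency, dt)
    z <- zerophase_filter(x * exp(-1i * phi_c), h2)
    a2 <- 2 * Mod(z)
    phi2 <- unwrap_phase(Arg(z))
    f2 <- band$inst_frequency + num_gradient(phi2, dt) / (2 * pi)
    f2 <- pmin(pmax(f2, band$center_hz - config$Fw), band$center_hz + config$Fw)
    f2 <- pmin(pmax(f2, 0), config$f_max)
    idx <- cbind(rows, round(f2 / config$grid_df) + 1L)
    amp_grid[idx] <- pmax(amp_grid[idx], a2)
  }
  structure(list(times = t, freqs = freqs, amplitude = amp_grid, fs_d = fs_d,
                 edge_s = (config$filter_len - 1) * dt),
            class = "ppg_tfs")
}

#' @export
print.ppg_tfs <- function(x, ...) {
  cat(sprintf("VFCDM time-frequency spectrum: %d time samples x %d frequency bins (%g-%g Hz), fs_d %g Hz, edge %g s\n",
              length(x$times), length(x$freqs), min(x$freqs), max(x$freqs),
              x$fs_d, x$edge_s))
  invisible(x)
}

#' @export
plot.ppg_tfs <- function(x, ...) {
  graphics::image(x$times, x$freqs, x$amplitude, xlab = "Time (s)",
                  ylab = "Frequency (Hz)", main = "VFCDM TFS", ...)
  invisible(x)
}

# indices of time samples outside the filter-edge transients
tfs_interior <- function(tfs) {
  n_edge <- round(tfs$edge_s * tfs$fs_d)
  n <- length(tfs$times)
  if (2 * n_edge >= n) stopf("spectrum has no interior samples")
  (n_edge + 1):(n - n_edge)
}

#' Band-maximum amplitude trace of a spectrum
#'
#' For each interior time sample, the maximum spectral amplitude over a
#' frequency band; the quantity tracked over time as AM_HR when the band is
#' the heart-rate band.
#'
#' @param tfs a `ppg_tfs`.
#' @param f_lo,f_hi band limits in Hz.
#' @return Numeric vector, one value per interior time sample.
#' @export
tfs_band_max <- function(tfs, f_lo, f_hi) {
  sel <- tfs$freqs >= f_lo & tfs$freqs <= f_hi
  if (!any(sel)) stopf("band [%g, %g] Hz contains no grid frequencies", f_lo, f_hi)
  apply(tfs$amplitude[tfs_interior(tfs), sel, drop = FALSE], 1, max)
}
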