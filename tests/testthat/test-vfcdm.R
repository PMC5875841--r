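# VFCDM: decimation, fixed-frequency demodulation, and the two-stage
# time-frequency spectrum, validated against analytic-signal/FFT oracles.

tone <- function(f, dur, fs, amp = 1) {
  amp * sin(2 * pi * f * (0:(dur * fs - 1)) / fs)
}

test_that("decimation preserves in-band tones and suppresses out-of-band ones", {
  x <- tone(1.2, 120, 80)
  y <- decimate_ppg(x, 80, 20)
  expect_length(y, 120 * 20)
  expect_equal(dft_amplitude(y, 20, 1.2), 1, tolerance = 0.01)
  hi <- tone(9.5, 120, 80)
  yh <- decimate_ppg(hi, 80, 20)
  expect_lt(sqrt(mean(yh^2)) / sqrt(mean(hi^2)), 0.05)
  expect_error(decimate_ppg(x, 80, 33), "integer multiple")
})

test_that("fixed CDM recovers tone amplitude and instantaneous frequency", {
  x <- tone(1.2, 240, 20)
  comps <- fixed_cdm(x, 20)
  centers <- sapply(comps, `[[`, "center_hz")
  n <- length(x)
  interior <- round(0.1 * n):round(0.9 * n)
  b <- comps[[which(centers == 1.0)]]
  expect_equal(median(b$inst_amplitude[interior]), 1, tolerance = 0.05)
  expect_lt(abs(median(b$inst_frequency[interior]) - 1.2), 0.05)
  # zero input -> identically zero amplitudes
  z <- fixed_cdm(rep(0, 2400), 20)
  expect_true(all(sapply(z, function(b) all(b$inst_amplitude == 0))))
  expect_error(fixed_cdm(rep(0, 100), 20), "too short")
})

test_that("two tones land in their own bands, remote bands stay silent", {
  x <- tone(0.3, 240, 20) + tone(1.2, 240, 20)
  comps <- fixed_cdm(x, 20)
  n <- 240 * 20
  interior <- round(0.1 * n):round(0.9 * n)
  Fw <- 0.5
  for (b in comps) {
    med <- median(b$inst_amplitude[interior])
    in_window <- min(abs(b$center_hz - c(0.3, 1.2))) < Fw
    if (abs(b$center_hz - 0.5) < 1e-9 || abs(b$center_hz - 1.0) < 1e-9) {
      expect_equal(med, 1, tolerance = 0.05)
    } else if (!in_window) {
      expect_lt(med, 0.1)
    }
  }
})

test_that("stage 1 is linear in its input", {
  set.seed(8)
  x <- tone(0.9, 120, 20)
  y <- tone(1.7, 120, 20, amp = 0.5)
  ca <- fixed_cdm(2 * x + 3 * y, 20)
  cx <- fixed_cdm(x, 20)
  cy <- fixed_cdm(y, 20)
  for (i in seq_along(ca)) {
    lhs <- ca[[i]]$inst_amplitude * exp(1i * ca[[i]]$inst_phase)
    rhs <- 2 * cx[[i]]$inst_amplitude * exp(1i * cx[[i]]$inst_phase) +
      3 * cy[[i]]$inst_amplitude * exp(1i * cy[[i]]$inst_phase)
    expect_lt(max(Mod(lhs - rhs)) / max(Mod(rhs)), 1e-8)
  }
})

test_that("stage-1 components approximately reconstruct a band-limited signal", {
  x <- tone(0.9, 240, 20) + 0.7 * tone(1.6, 240, 20) + 0.4 * tone(3.1, 240, 20)
  rec <- cdm_reconstruct(fixed_cdm(x, 20))
  n <- length(x)
  interior <- round(0.1 * n):round(0.9 * n)
  err <- sqrt(mean((rec[interior] - x[interior])^2)) / sqrt(mean(x[interior]^2))
  expect_lt(err, 0.05)
})

test_that("TFS ridge calibrates on a pure tone", {
  x <- tone(1.2, 120, 20)
  tfs <- vfcdm_tfs(x, 20)
  n <- length(x)
  interior <- round(0.1 * n):round(0.9 * n)
  ridge_amp <- apply(tfs$amplitude[interior, ], 1, max)
  ridge_freq <- tfs$freqs[apply(tfs$amplitude[interior, ], 1, which.max)]
  expect_true(all(abs(ridge_amp - 1) < 0.05))
  expect_true(all(abs(ridge_freq - 1.2) <= 0.1))
  # all-zero input -> all-zero spectrum
  expect_true(all(vfcdm_tfs(rep(0, 1200), 20)$amplitude == 0))
})

test_that("TFS ridge tracks a linear chirp", {
  fs_d <- 20
  t <- (0:(120 * fs_d - 1)) / fs_d
  k <- (1.6 - 0.8) / 120
  x <- sin(2 * pi * (0.8 * t + k * t^2 / 2))
  tfs <- vfcdm_tfs(x, fs_d)
  n <- length(x)
  interior <- round(0.1 * n):round(0.9 * n)
  ridge_freq <- tfs$freqs[apply(tfs$amplitude[interior, ], 1, which.max)]
  f_true <- 0.8 + k * t[interior]
  expect_lt(sqrt(mean((ridge_freq - f_true)^2)), 0.1)
})

test_that("amplitude calibration holds across the analysis band", {
  # worst case includes a tone exactly midway between stage-1 centers
  n <- 120 * 20
  interior <- round(0.1 * n):round(0.9 * n)
  for (f in c(0.8, 1.25, 2.3, 6.75)) {
    tfs <- vfcdm_tfs(tone(f, 120, 20, amp = 0.7), 20)
    ridge <- apply(tfs$amplitude[interior, ], 1, max)
    expect_equal(median(ridge), 0.7, tolerance = 0.05)
  }
})

test_that("a respiratory component is visible below 0.5 Hz in the TFS", {
  cfg <- sim_config(duration_s = 120, resp_hz = 0.3, resp_mod_frac = 0.25,
                    wander_amp = 0, channel_noise_sd = 0)
  x <- decimate_ppg(simulate_record(cfg)$samples[, 1], 80, 20)
  tfs <- vfcdm_tfs(x, 20)
  low <- tfs$freqs > 0 & tfs$freqs < 0.5
  interior <- tfs$times > 12 & tfs$times < 108
  expect_gt(max(tfs$amplitude[interior, low]), 0.1)
})

test_that("configuration invariants are enforced", {
  expect_error(vfcdm_config(Fv = 0.6), "Fv < Fw")
  expect_error(vfcdm_config(Fw = 0.7), "integer number of bands")
  expect_error(vfcdm_config(filter_len = 160), "odd")
  expect_error(vfcdm_config(grid_df = 0.2), "grid_df")
})
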