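# Windowing scheme, AM_HR extraction, trend features, truncation.

test_that("sequence extraction follows the 2-minute block scheme", {
  rec <- simulate_record(sim_config(duration_s = 600, seed = 2))
  seqs <- extract_sequences(rec)
  expect_length(seqs, 5)
  expect_equal(sapply(seqs, `[[`, "start_s"), c(0, 120, 240, 360, 480))
  expect_length(seqs[[1]]$samples, 120 * 80)
  # custom starts
  seqs2 <- extract_sequences(rec, window_scheme(starts = c(0, 300)))
  expect_length(seqs2, 2)
  # too short for a trend
  short <- simulate_record(sim_config(duration_s = 130, seed = 2))
  expect_error(extract_sequences(short), "too short")
})

test_that("window scheme invariants", {
  expect_error(window_scheme(win_len_s = 120), "win_len_s")
  expect_error(window_scheme(shift_s = 7), "divisible")
  expect_error(hr_band(f_lo = 0.3), "respiratory")
  expect_error(hr_band(f_lo = 2, f_hi = 1), "f_hi")
})

test_that("mean AM_HR recovers tone and envelope means", {
  fs <- 80
  t <- (0:(120 * fs - 1)) / fs
  x <- sin(2 * pi * 1.2 * t)
  expect_equal(amhr_from_sequence(x, fs), 1, tolerance = 0.05)
  expect_identical(amhr_from_sequence(rep(0, 120 * fs), fs), 0)
  # linearly decaying envelope 1 -> 0.8: time-average 0.9
  env <- 1 - 0.2 * t / t[length(t)]
  expect_equal(amhr_from_sequence(env * x, fs), 0.9, tolerance = 0.05)
  expect_error(amhr_from_sequence(x, fs, band = hr_band(5, 12)), "Nyquist")
})

test_that("trend features match closed forms on collinear and constant series", {
  s <- amhr_series(c(0, 120, 240, 360), c(5.0, 4.9, 4.8, 4.7))
  f <- trend_features(s)
  expect_equal(f$slope, -1 / 1200, tolerance = 1e-12)
  expect_equal(f$r2, 1, tolerance = 1e-12)
  expect_equal(f$abs_change, -0.3, tolerance = 1e-12)
  expect_equal(f$pct_change, -6.0, tolerance = 1e-12)
  # constant series: no trend evidence
  f0 <- trend_features(amhr_series(c(0, 120, 240, 360), c(2, 2, 2, 2)))
  expect_identical(unlist(f0, use.names = FALSE), c(0, 0, 0, 0))
  # zero first value: percentage change undefined
  expect_error(trend_features(amhr_series(c(0, 120), c(0, 1))), "undefined")
})

test_that("trend OLS agrees with a normal-equations oracle", {
  tt <- c(0, 120, 240, 360, 480)
  vv <- c(3.0, 3.4, 2.9, 3.3, 2.8)
  f <- trend_features(amhr_series(tt, vv))
  o <- ols_oracle(tt, vv)
  expect_equal(f$slope, o$slope, tolerance = 1e-10)
  expect_equal(f$r2, o$r2, tolerance = 1e-10)
})

test_that("time reversal negates slope and changes, preserves r-squared", {
  tt <- c(0, 120, 240, 360, 480)
  vv <- c(3.0, 3.4, 2.9, 3.3, 2.8)
  f <- trend_features(amhr_series(tt, vv))
  fr <- trend_features(amhr_series(tt, rev(vv)))
  expect_equal(fr$slope, -f$slope, tolerance = 1e-12)
  expect_equal(fr$abs_change, -f$abs_change, tolerance = 1e-12)
  expect_equal(fr$r2, f$r2, tolerance = 1e-12)
  expect_identical(sign(fr$pct_change), -sign(f$pct_change))
})

test_that("featurization is scale-equivariant", {
  rec <- simulate_record(sim_config(duration_s = 600, amp_decay_frac = 0.4,
                                    seed = 6))
  scaled <- rec
  scaled$samples <- 2.5 * rec$samples
  f1 <- featurize_record(rec)$features
  f2 <- featurize_record(scaled)$features
  expect_equal(f2$slope, 2.5 * f1$slope, tolerance = 1e-6)
  expect_equal(f2$abs_change, 2.5 * f1$abs_change, tolerance = 1e-6)
  expect_equal(f2$r2, f1$r2, tolerance = 1e-6)
  expect_equal(f2$pct_change, f1$pct_change, tolerance = 1e-6)
})

test_that("featurized records reflect their generated envelope trend", {
  bl <- featurize_record(simulate_record(sim_config(duration_s = 600,
                                                    amp_decay_frac = 0.5,
                                                    seed = 31)))
  expect_lt(bl$features$slope, 0)
  expect_equal(bl$features$pct_change, -50, tolerance = 10)
  expect_gt(bl$features$r2, 0.9)
  nbl <- featurize_record(simulate_record(sim_config(duration_s = 600,
                                                     amp_decay_frac = 0,
                                                     seed = 32)))
  expect_lt(abs(nbl$features$pct_change), 5)
})

test_that("truncation keeps the leading portion and flags no-ops", {
  rec <- simulate_record(sim_config(duration_s = 1200, seed = 13))
  tr <- truncate_record(rec, 600)
  expect_equal(nrow(tr$samples) / tr$fs, 600)
  expect_identical(attr(tr, "truncated_to_s"), 600)
  expect_lt(max(abs(tr$samples - rec$samples[1:(600 * 80), ])), 1e-15)
  shortest <- truncate_record(rec, 240)
  expect_equal(nrow(shortest$samples) / shortest$fs, 240)
  expect_warning(noop <- truncate_record(rec, 2000), "no-op")
  expect_identical(attr(noop, "truncation_noop"), TRUE)
  expect_identical(nrow(noop$samples), nrow(rec$samples))
  expect_error(truncate_record(rec, 100), "240")
})
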