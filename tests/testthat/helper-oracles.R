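# Independent oracles and shared fixtures, all built in code.

# FFT-based analytic signal (Hilbert transform); independent of the
# package's demodulation/FIR pathway.
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

hilbert_envelope <- function(x) Mod(analytic_signal(x))

# exact single-frequency DFT amplitude (use frequencies with an integer
# number of cycles in the window)
dft_amplitude <- function(x, fs, f) {
  n <- length(x)
  t <- (seq_len(n) - 1) / fs
  2 * Mod(sum(x * exp(-2i * pi * f * t))) / n
}

# OLS slope and r-squared by explicit normal equations
ols_oracle <- function(t, v) {
  A <- cbind(1, t)
  beta <- solve(t(A) %*% A, t(A) %*% v)
  fit <- A %*% beta
  list(slope = beta[2], r2 = 1 - sum((v - fit)^2) / sum((v - mean(v))^2))
}

# Featurized default synthetic cohort, computed once per test session and
# shared by the end-to-end tests.
.shared <- new.env(parent = emptyenv())
shared_cohort <- function() {
  if (is.null(.shared$cohort)) .shared$cohort <- simulate_cohort(cohort_spec(seed = 1))
  .shared$cohort
}
shared_cohort_features <- function() {
  if (is.null(.shared$features)) .shared$features <- featurize_cohort(shared_cohort())
  .shared$features
}

# quick synthetic feature table with a class gap, for protocol tests that
# do not need the signal pipeline
mock_feature_table <- function(n_bl = 29, n_nbl = 65, gap = TRUE, seed = 5) {
  ppgtrend:::with_seed(seed, {
    bl_pct <- if (gap) stats::runif(n_bl, -55, -27) else stats::rnorm(n_bl, 0, 5)
    data.frame(
      record_id = sprintf("r%03d", seq_len(n_bl + n_nbl)),
      label = rep(c("BL", "NBL"), c(n_bl, n_nbl)),
      r2 = stats::runif(n_bl + n_nbl),
      slope = c(bl_pct, stats::rnorm(n_nbl, 0, 5)) * 1e-5,
      pct_change = c(bl_pct, stats::rnorm(n_nbl, 0, 2.5)),
      abs_change = c(bl_pct, stats::rnorm(n_nbl, 0, 2.5)) / 100)
  })
}
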