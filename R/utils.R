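# Internal helpers shared across modules.

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' Evaluate an expression under a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards, so seeded simulation and
#' resampling never perturb the global random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% 2147480009))
  expr
}

# smallest odd integer >= x
round_odd <- function(x) {
  n <- ceiling(x)
  if (n %% 2 == 0) n + 1L else as.integer(n)
}

# phase unwrapping: remove 2*pi jumps from a wrapped phase sequence
unwrap_phase <- function(p) {
  if (length(p) < 2) return(p)
  d <- diff(p)
  d <- d - 2 * pi * round(d / (2 * pi))
  cumsum(c(p[1], d))
}

# numerical derivative: central differences, one-sided at the ends
num_gradient <- function(x, dt) {
  n <- length(x)
  if (n < 2) return(rep(0, n))
  g <- numeric(n)
  g[1] <- (x[2] - x[1]) / dt
  g[n] <- (x[n] - x[n - 1]) / dt
  if (n > 2) g[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / (2 * dt)
  g
}

# cumulative trapezoidal integral of y sampled at spacing dt, starting at 0
cum_trapz <- function(y, dt) {
  n <- length(y)
  if (n < 2) return(rep(0, n))
  c(0, cumsum((y[-1] + y[-n]) / 2)) * dt
}
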