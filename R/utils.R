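# Internal helpers: seeding, random draws, time grids.

# Deterministic per-unit seed derived from a master seed. Keeps results
# reproducible while letting each trial/stage own an independent stream.
derive_seed <- function(seed, index, stage = 0L) {
  (as.integer(seed) %% 1000003L) * 1009L + as.integer(index) * 7919L +
    as.integer(stage) * 104729L
}

with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

# Ex-Gaussian draw: normal plus independent exponential component.
rexgauss <- function(n, mu, sigma, tau) {
  stats::rnorm(n, mu, sigma) + stats::rexp(n, rate = 1 / tau)
}

# Zero-truncated normal via inverse-CDF (exact, vectorized).
rtruncnorm0 <- function(n, mu, sigma) {
  lo <- stats::pnorm(0, mu, sigma)
  u <- stats::runif(n, lo, 1)
  stats::qnorm(u, mu, sigma)
}

# Mean of the zero-truncated normal (generator ground truth for SSRT).
truncnorm0_mean <- function(mu, sigma) {
  a <- -mu / sigma
  mu + sigma * stats::dnorm(a) / (1 - stats::pnorm(a))
}

# Uniform sample-time grid (ms relative to the go signal).
time_grid_ms <- function(fs, pre_ms, post_ms) {
  dt <- 1000 / fs
  seq(-pre_ms, post_ms, by = dt)
}

ms_to_index <- function(t_ms, fs, t0_ms) {
  round((t_ms - t0_ms) * fs / 1000) + 1L
}

index_to_ms <- function(i, fs, t0_ms) {
  t0_ms + (i - 1L) * 1000 / fs
}

`%||%` <- function(a, b) if (is.null(a)) b else a
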