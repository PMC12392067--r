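# Shared fixtures: small parameter sets, signal builders, and the
# brute-force burst-detector oracle.

fast_synth <- function(...) synth_params(fs = 1000, ...)

small_race <- function(...) race_params(n_blocks = 2, trials_per_block = 48, ...)

make_signal <- function(samples, fs = 1000, t0_ms = 0,
                        channel = "agonist") {
  list(channel = channel, fs = fs, t0_ms = t0_ms, samples = samples)
}

# Brute-force detector oracle: every candidate interval found by naive
# per-sample scanning; the same published strongest-first grouping rule,
# implemented independently with plain loops.
oracle_detect <- function(env, fs, t0_ms, ref, peak_frac, edge_frac,
                          dwell_ms, edge_reference = "burst_peak") {
  n <- length(env)
  dwell <- max(1, round(dwell_ms * fs / 1000))
  is_cand <- logical(n)
  for (i in seq_len(n)) {
    l <- if (i > 1) env[i - 1] else -Inf
    r <- if (i < n) env[i + 1] else -Inf
    if (env[i] >= peak_frac * ref && env[i] > l && env[i] >= r)
      is_cand[i] <- TRUE
  }
  cand <- which(is_cand)
  if (length(cand) == 0)
    return(data.frame(onset = integer(0), offset = integer(0),
                      peak = integer(0)))
  interval <- function(p) {
    th <- edge_frac * (if (edge_reference == "burst_peak") env[p] else ref)
    onset <- 1L
    if (p > dwell) {
      for (e in (p - 1):dwell) {
        if (all(env[(e - dwell + 1):e] < th)) { onset <- e + 1L; break }
      }
    }
    offset <- n
    if (p + dwell <= n) {
      for (s in (p + 1):(n - dwell + 1)) {
        if (all(env[s:(s + dwell - 1)] < th)) { offset <- s - 1L; break }
      }
    }
    c(onset, offset)
  }
  ord <- cand[order(-env[cand], cand)]
  used <- rep(FALSE, length(ord))
  res <- NULL
  for (k in seq_along(ord)) {
    if (used[k]) next
    iv <- interval(ord[k])
    used[ord >= iv[1] & ord <= iv[2]] <- TRUE
    res <- rbind(res, c(iv[1], iv[2], ord[k]))
  }
  res <- res[order(res[, 1], res[, 3]), , drop = FALSE]
  if (nrow(res) > 1) {
    keep <- rep(TRUE, nrow(res))
    last <- 1
    for (k in 2:nrow(res)) {
      if (res[k, 1] <= res[last, 2]) {
        if (env[res[k, 3]] > env[res[last, 3]]) keep[last] <- FALSE
        else keep[k] <- FALSE
        if (keep[k]) last <- k
      } else last <- k
    }
    res <- res[keep, , drop = FALSE]
  }
  data.frame(onset = res[, 1], offset = res[, 2], peak = res[, 3])
}

# Random bursty envelope for property tests: baseline noise magnitude with
# a random number of smooth raised-cosine bumps.
random_envelope <- function(n = 300, fs = 1000, max_bursts = 3,
                            noise = 0.02) {
  env <- abs(stats::rnorm(n, 0, noise))
  for (b in seq_len(sample(0:max_bursts, 1))) {
    centre <- sample(seq_len(n), 1)
    width <- sample(20:80, 1)
    amp <- stats::runif(1, 0.05, 1.2)
    idx <- pmax(1, centre - width):pmin(n, centre + width)
    env[idx] <- env[idx] +
      amp * 0.5 * (1 + cos(pi * (idx - centre) / width))
  }
  env
}
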