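# EMG preprocessing and burst detection.

test_that("TMS artifact interpolation bridges the window linearly", {
  # constant signal: unchanged
  sig <- make_signal(rep(2, 200))
  out <- interpolate_tms_artifact(sig, 100)
  expect_equal(out$samples, sig$samples)
  # spike inside the window on a flat baseline: flattened
  sig2 <- make_signal(rep(0, 200))
  sig2$samples[101] <- 50
  out2 <- interpolate_tms_artifact(sig2, 100)
  expect_equal(out2$samples, rep(0, 200))
  # a ramp is continued exactly
  sig3 <- make_signal(seq(0, 1.99, by = 0.01))
  withspike <- sig3
  withspike$samples[100:102] <- 9
  out3 <- interpolate_tms_artifact(withspike, 99.5)
  expect_equal(out3$samples, sig3$samples, tolerance = 1e-12)
  # window outside the span errors
  expect_error(interpolate_tms_artifact(sig, 300), "span")
})

test_that("RMS envelope matches closed forms", {
  p <- envelope_params(rms_window_ms = 20)
  # constant c -> |c| at interior samples
  sig <- make_signal(rep(-3, 500))
  expect_equal(rms_envelope(sig, p)$samples, rep(3, 500))
  # sine of amplitude A with window >> period -> A / sqrt(2)
  fs <- 1000
  t <- seq_len(2000) / fs
  sine <- make_signal(2 * sin(2 * pi * 200 * t), fs = fs)
  env <- rms_envelope(sine, envelope_params(rms_window_ms = 100))$samples
  expect_equal(mean(env[500:1500]), 2 / sqrt(2), tolerance = 0.01)
  # white noise of sd sigma -> envelope concentrates on sigma as the
  # window grows
  set.seed(99)
  noise <- make_signal(rnorm(5000, 0, 0.4))
  env2 <- rms_envelope(noise, envelope_params(rms_window_ms = 500))$samples
  expect_equal(mean(env2), 0.4, tolerance = 0.02)
  expect_error(rms_envelope(make_signal(1:5), envelope_params(rms_window_ms = 50)),
               "longer")
})

test_that("burst detector handles canonical envelopes", {
  p <- burst_params(peak_frac = 0.15, edge_frac = 0.10)
  # flat zero envelope: nothing
  expect_equal(nrow(detect_bursts(make_signal(numeric(400)), 1, p)), 0)
  # rectangular pulse over [100, 200] ms: one burst with step edges
  env <- numeric(400)
  env[101:201] <- 1
  b <- detect_bursts(make_signal(env), 1, p)
  expect_equal(nrow(b), 1)
  expect_equal(b$onset_ms, 100, tolerance = 1.01)
  expect_equal(b$offset_ms, 200, tolerance = 1.01)
  expect_equal(b$peak_amp_norm, 1)
  # two pulses with a 100 ms sub-threshold gap: two bursts
  env2 <- numeric(500)
  env2[101:150] <- 1
  env2[251:300] <- 0.8
  b2 <- detect_bursts(make_signal(env2), 1, p)
  expect_equal(nrow(b2), 2)
  # the same pulses separated by only 10 ms (< dwell): one merged burst
  env3 <- numeric(500)
  env3[101:150] <- 1
  env3[161:210] <- 0.8
  b3 <- detect_bursts(make_signal(env3), 1, p)
  expect_equal(nrow(b3), 1)
  expect_equal(b3$onset_ms, 100, tolerance = 1.01)
  expect_equal(b3$offset_ms, 209, tolerance = 1.01)
})

test_that("detector agrees exactly with the brute-force oracle", {
  p <- burst_params(peak_frac = 0.15, edge_frac = 0.10, min_dwell_ms = 20)
  set.seed(7)
  for (r in 1:200) {
    env <- random_envelope()
    got <- detect_bursts(make_signal(env), 1, p)
    want <- oracle_detect(env, 1000, 0, 1, p$peak_frac, p$edge_frac,
                          p$min_dwell_ms)
    expect_equal(nrow(got), nrow(want), info = paste("envelope", r))
    if (nrow(got) > 0) {
      expect_equal(got$onset_ms, (want$onset - 1) * 1,
                   info = paste("onset, envelope", r))
      expect_equal(got$offset_ms, (want$offset - 1) * 1,
                   info = paste("offset, envelope", r))
      expect_equal(got$peak_ms, (want$peak - 1) * 1,
                   info = paste("peak, envelope", r))
    }
  }
})

test_that("raising the peak threshold never increases the burst count", {
  set.seed(21)
  for (r in 1:50) {
    env <- make_signal(random_envelope())
    n_prev <- Inf
    for (pf in c(0.1, 0.2, 0.4, 0.8)) {
      n <- nrow(detect_bursts(env, 1, burst_params(peak_frac = pf,
                                                   edge_frac = 0.05)))
      expect_lte(n, n_prev)
      n_prev <- n
    }
  }
})

test_that("envelope normalization is a linear rescaling to percent", {
  env <- make_signal(c(0, 0.5, 1, 0.25))
  expect_equal(normalize_envelope(env, 1)$samples, c(0, 50, 100, 25))
  expect_equal(max(normalize_envelope(env, max(env$samples))$samples), 100)
  expect_equal(max(normalize_envelope(env, 2 * max(env$samples))$samples), 50)
  set.seed(3)
  x <- abs(rnorm(100))
  a <- normalize_envelope(make_signal(x), 0.7)$samples
  b <- normalize_envelope(make_signal(3 * x), 0.7)$samples
  expect_equal(b, 3 * a, tolerance = 1e-12)
})

test_that("IQR rule flags by linearly interpolated quartiles", {
  expect_equal(exclude_timing_outliers(c(1, 2, 3, 4, 100)),
               c(FALSE, FALSE, FALSE, FALSE, TRUE))
  expect_false(any(exclude_timing_outliers(rep(5, 10))))
  # Gaussian sample: about 0.7% flagged per tail
  set.seed(11)
  v <- rnorm(1e4)
  frac <- mean(exclude_timing_outliers(v))
  expect_gt(frac, 0.006)
  expect_lt(frac, 0.024)
  expect_warning(exclude_timing_outliers(c(1, 2, 3)), "fewer than 4")
})

test_that("early antagonist bursts near the stop signal are excluded", {
  p <- burst_params()
  b <- data.frame(onset_ms = c(230, 260), peak_ms = c(240, 280),
                  offset_ms = c(250, 320), peak_amp = c(1, 1),
                  peak_amp_norm = c(1, 1))
  # stop signal at 200: onset at stop+30 excluded, stop+60 kept
  out <- exclude_early_antagonist(b, 200, p)
  expect_equal(out$onset_ms, 260)
  # no antagonist burst: trial kept with missing antagonist timing
  empty <- b[0, ]
  expect_equal(nrow(exclude_early_antagonist(empty, 200, p)), 0)
})

test_that("zero-phase filtering preserves burst timing on synthetic EMG", {
  sp <- fast_synth()
  ep <- envelope_params(bp_high = 450, bs_band = c(48, 52))
  t <- seq(-200, 800, by = 1)
  env_true <- stopdyn:::phasic_envelope(t, 100, 50, 120)
  set.seed(5)
  raw <- env_true * rnorm(length(t)) + 0.01 * rnorm(length(t)) +
    0.005 * sin(2 * pi * 50 * t / 1000)
  env <- preprocess_emg(make_signal(raw, t0_ms = -200), ep)
  b <- detect_bursts(env, 1, burst_params(0.15, 0.10))
  expect_equal(nrow(b), 1)
  expect_lt(abs(b$peak_ms - 150), 25)
  expect_lt(abs(b$onset_ms - 100), 15)
})
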