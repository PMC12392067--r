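# MEP amplitude extraction, gating, time course, conduction time.

test_that("peak-to-peak measurement reads the 18-48 ms window", {
  fs <- 4000
  t <- seq(-200, 600, by = 1000 / fs)
  x <- numeric(length(t))
  # sine burst of +/- 0.5 mV centred at tms + 30
  w <- t >= 125 & t <= 135
  x[w] <- 0.5 * sin(2 * pi * 200 * (t[w] - 125) / 1000)
  sig <- make_signal(x, fs = fs, t0_ms = -200)
  expect_equal(measure_mep(sig, 100), 1.0, tolerance = 0.01)
  expect_equal(measure_mep(make_signal(numeric(3201), fs = fs, t0_ms = -200),
                           100), 0)
  expect_error(measure_mep(sig, 580), "span")
})

test_that("pre-TMS gate applies a strict threshold", {
  fs <- 1000
  mk <- function(level) make_signal(rep(level, 600), fs = fs, t0_ms = -200)
  expect_true(gate_pre_tms(mk(0.01), 200))
  expect_false(gate_pre_tms(mk(0.1), 200))
  expect_false(gate_pre_tms(mk(0.05), 200))  # boundary: excluded
  # monotonicity: raising the threshold never decreases inclusions
  set.seed(31)
  sigs <- lapply(1:40, function(i)
    make_signal(rnorm(600, 0, runif(1, 0.01, 0.1)), fs = fs, t0_ms = -200))
  n_prev <- -1
  for (th in c(0.02, 0.05, 0.1, 0.2)) {
    n <- sum(vapply(sigs, gate_pre_tms, logical(1), tms_time_ms = 200,
                    threshold_mv = th))
    expect_gte(n, n_prev)
    n_prev <- n
  }
})

test_that("suppression time course normalizes to the go-signal baseline", {
  m <- expand.grid(trial_id = 1:8,
                   trial_type = c("go", "early_stop", "late_stop"),
                   tms_timepoint_ms = c(0, 100, 150),
                   stringsAsFactors = FALSE)
  m <- m[!(m$trial_type != "go" & m$tms_timepoint_ms == 0), ]
  m$p2p_mv <- 1.3
  m$included <- TRUE
  tc <- suppression_timecourse(m)
  expect_equal(attr(tc, "baseline_mv"), 1.3)
  expect_true(all(tc$mean_ratio == 1))
  # cells below the trial minimum are flagged missing
  tc2 <- suppression_timecourse(m, min_trials = 10)
  expect_true(all(is.na(tc2$mean_ratio)))
  expect_true(all(tc2$n_included == 8))
})

test_that("conduction time is the minimum onset latency", {
  expect_equal(conduction_time(c(24.1, 23.3, 25.0)), 23.3)
  expect_equal(conduction_time(9.6), 9.6)
  expect_error(conduction_time(numeric(0)), "no onset latencies")
})

test_that("measured MEP amplitudes track the injected generative truth", {
  sp <- fast_synth()
  blank <- make_signal(numeric(1500), fs = 1000, t0_ms = -200,
                       channel = "task_irrelevant")
  truth <- data.frame(suppression_depth = 0.3, supp_win_lo_ms = 150,
                      supp_win_hi_ms = 300)
  true_amp <- est_amp <- numeric(100)
  for (i in 1:100) {
    s <- synth_mep(blank, tms_time_ms = 300, tms_rel_stop_ms = 100,
                   truth_row = truth, synth = sp, seed = i)
    true_amp[i] <- attr(s, "true_p2p_mv")
    est_amp[i] <- measure_mep(s, 300)
  }
  expect_lt(max(abs(est_amp - true_amp) / true_amp), 0.01)
})
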