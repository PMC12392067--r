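# Race-model generator: staircase, outcomes, determinism, forward model.

test_that("staircase steps move the SSD by one step with a floor at zero", {
  expect_equal(update_ssd(200, TRUE, 50), 250)
  expect_equal(update_ssd(200, FALSE, 50), 150)
  expect_equal(update_ssd(0, FALSE, 50), 0)
  expect_equal(update_ssd(20, FALSE, 50), 0)
  expect_error(update_ssd(200, TRUE, -10), "positive")
  expect_error(update_ssd(-5, TRUE, 10))
})

test_that("identical seeds give byte-identical simulations", {
  rp <- small_race()
  sp <- fast_synth()
  a <- simulate_experiment(rp, sp, seed = 123)
  b <- simulate_experiment(rp, sp, seed = 123)
  expect_identical(a$trials, b$trials)
  expect_identical(a$truth, b$truth)
  sa <- synth_trial_signals(a$truth[1, ], a$trials[1, ], sp, seed = 5)
  sb <- synth_trial_signals(b$truth[1, ], b$trials[1, ], sp, seed = 5)
  expect_identical(sa$agonist$samples, sb$agonist$samples)
  expect_false(identical(
    a$trials, simulate_experiment(rp, sp, seed = 124)$trials))
})

test_that("degenerate race parameters give all-or-nothing stopping", {
  sp <- fast_synth()
  # stop finishing times essentially 0, SSD locked at 0: stop always wins
  rp <- race_params(stop_mu = 1e-6, stop_sigma = 1e-9,
                    p_trigger_failure = 0, ssd_init = 0, ssd_step = 1e-9,
                    n_blocks = 1, trials_per_block = 48)
  sim <- simulate_experiment(rp, sp, seed = 2)
  stop_lbl <- sim$trials$outcome_label[sim$trials$trial_type == "stop"]
  expect_true(all(stop_lbl == "early_stop"))
  # trigger failures on every stop trial: no successful stops, SSD -> floor
  rp2 <- small_race(p_trigger_failure = 1)
  sim2 <- simulate_experiment(rp2, sp, seed = 2)
  stop_tr <- sim2$trials[sim2$trials$trial_type == "stop", ]
  expect_true(all(stop_tr$outcome_label == "trigger_failure"))
  expect_equal(utils::tail(stop_tr$ssd_ms, 1), 0)
})

test_that("go-trial TMS is yoked to the preceding stop trial's SSD", {
  rp <- small_race()
  sim <- simulate_experiment(rp, fast_synth(), seed = 31)
  tt <- sim$trials
  last_ssd <- rp$ssd_init
  for (i in seq_len(nrow(tt))) {
    if (tt$trial_type[i] == "stop") last_ssd <- tt$ssd_ms[i]
    else expect_equal(tt$ssd_ms[i], last_ssd)
  }
  # non-baseline go TMS pulses sit at yoked SSD + a probe time point
  go_tms <- tt$trial_type == "go" & !is.na(tt$tms_time_ms) &
    tt$tms_time_ms > 0
  rel <- tt$tms_time_ms[go_tms] - tt$ssd_ms[go_tms]
  expect_true(all(round(rel, 6) %in% c(100, 150, 200, 250, 300)))
})

test_that("go finishing times on stop trials share the go distribution", {
  rp <- race_params(n_blocks = 25, trials_per_block = 96)
  sim <- simulate_experiment(rp, fast_synth(), seed = 8, tms = FALSE)
  is_stop <- sim$trials$trial_type == "stop"
  go_rt <- sim$truth$go_finish_ms[!is_stop]
  stop_latent <- sim$truth$go_finish_ms[is_stop]
  ks <- suppressWarnings(stats::ks.test(go_rt[!is.na(go_rt)],
                                        stop_latent[!is.na(stop_latent)]))
  expect_gt(ks$p.value, 0.001)
})

test_that("long-run stopping probability converges to one half", {
  rp <- exp1_race_params()
  ps <- vapply(1:5, function(s) {
    sim <- simulate_experiment(rp, fast_synth(), seed = s, tms = FALSE)
    m <- sim$trials$trial_type == "stop"
    mean(sim$trials$outcome_label[m] == "early_stop")
  }, numeric(1))
  expect_gt(mean(ps), 0.47)
  expect_lt(mean(ps), 0.53)
})

test_that("noiseless go trial renders a smooth burst that drives a full reach", {
  sp <- fast_synth(noise_sd = 0, mains_amp = 0, kin_noise_px = 0)
  rp <- small_race(p_wrongdir = 0, p_omission = 0)
  sim <- simulate_experiment(rp, sp, seed = 4)
  i <- which(sim$trials$outcome_label == "correct_go")[1]
  sigs <- synth_trial_signals(sim$truth[i, ], sim$trials[i, ], sp, seed = 1)
  ag <- sigs$agonist$samples
  expect_true(all(ag >= 0))
  # rises once to a single phasic maximum at the latent peak time
  t <- seq(-sp$pre_ms, sp$post_ms, by = 1000 / sp$fs)
  expect_equal(t[which.max(ag)], sim$truth$agonist_peak_ms[i],
               tolerance = 2, ignore_attr = TRUE)
  x <- sigs$displacement$samples
  expect_true(max(x) >= sp$target_distance_px - sp$target_halfwidth_px)
  expect_true(all(diff(x) > -1e-9))  # monotone reach
})

test_that("early-stop truth without a burst renders a flat agonist channel", {
  sp <- fast_synth(noise_sd = 0, mains_amp = 0, kin_noise_px = 0)
  truth <- data.frame(
    trial_id = 1L, go_finish_ms = 520, stop_finish_ms = 180,
    triggered = TRUE, wrongdir = FALSE, cmd_offset_ms = 120,
    has_agonist_burst = FALSE, agonist_onset_ms = NA_real_,
    agonist_peak_ms = NA_real_, agonist_offset_ms = NA_real_,
    antagonist_onset_ms = NA_real_, antagonist_amp = NA_real_,
    ant_slow = FALSE, suppression_depth = 0.3, supp_win_lo_ms = 150,
    supp_win_hi_ms = 300, outcome_label = "early_stop")
  trial <- data.frame(trial_id = 1L, block = 1L, trial_type = "stop",
                      ssd_ms = 200, tms_time_ms = NA_real_, go_onset_ms = 0,
                      response = "none", rt_ms = NA_real_,
                      total_rt_ms = NA_real_, outcome_label = "early_stop")
  sigs <- synth_trial_signals(truth, trial, sp, seed = 1)
  expect_equal(max(abs(sigs$agonist$samples)), 0)
  expect_equal(max(abs(sigs$displacement$samples)), 0)
})

test_that("noiseless late stop peaks its velocity at the drive transition", {
  sp <- fast_synth(noise_sd = 0, mains_amp = 0, kin_noise_px = 0)
  rp <- small_race()
  sim <- simulate_experiment(rp, sp, seed = 12)
  idx <- which(sim$truth$outcome_label == "late_stop" &
                 sim$truth$has_agonist_burst)
  expect_gt(length(idx), 0)
  i <- idx[1]
  sigs <- synth_trial_signals(sim$truth[i, ], sim$trials[i, ], sp, seed = 1)
  vp <- attr(sigs$displacement, "vel_peak_ms")
  # velocity peak lies between the forced decline start and antagonist
  # braking onset (plus shallow smoothing slack)
  decline <- sim$truth$agonist_offset_ms[i] - sp$fall_ms
  expect_gte(vp, decline - 2)
  expect_lte(vp, sim$truth$agonist_offset_ms[i] + sp$ant_gap_ms + 25)
  # and the kinematic estimator recovers it exactly on the noiseless trace
  est <- kinematic_ssrt(list(sigs$displacement),
                        stop_times_ms = 0)$per_trial_ms
  expect_equal(est, vp, tolerance = 1.01 * 1000 / sp$fs)
})

test_that("MEP amplitudes follow the generative suppression model", {
  sp <- fast_synth()
  blank <- make_signal(numeric(1500), fs = 1000, t0_ms = -200,
                       channel = "task_irrelevant")
  truth0 <- data.frame(suppression_depth = 0, supp_win_lo_ms = 150,
                       supp_win_hi_ms = 300)
  truth1 <- data.frame(suppression_depth = 1, supp_win_lo_ms = 150,
                       supp_win_hi_ms = 300)
  # depth 1 inside the window: amplitude at the noise floor
  s1 <- synth_mep(blank, tms_time_ms = 400, tms_rel_stop_ms = 200,
                  truth_row = truth1, synth = sp, seed = 3)
  expect_equal(attr(s1, "true_p2p_mv"), 0)
  # depth 0: same expected amplitude inside and outside the window
  set.seed(41)
  amps_in <- draw_mep_amplitudes(4000, sp, suppressed = TRUE, depth = 0)
  amps_out <- draw_mep_amplitudes(4000, sp, suppressed = FALSE, depth = 0)
  expect_equal(mean(amps_in), mean(amps_out), tolerance = 0.05)
  expect_equal(mean(amps_out), sp$mep_base_mv, tolerance = 0.05)
  # depth 0.3 at a probed time point: mean ratio about 0.7 over 500 trials
  set.seed(42)
  supp <- draw_mep_amplitudes(500, sp, suppressed = TRUE, depth = 0.3)
  base <- draw_mep_amplitudes(500, sp, suppressed = FALSE, depth = 0.3)
  expect_equal(mean(supp) / mean(base), 0.7, tolerance = 0.05)
  # measured p2p of an injected MEP equals the drawn amplitude
  s0 <- synth_mep(blank, tms_time_ms = 400, tms_rel_stop_ms = NA,
                  truth_row = truth0, synth = sp, seed = 7)
  expect_equal(measure_mep(s0, 400), attr(s0, "true_p2p_mv"),
               tolerance = 1e-9)
})
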