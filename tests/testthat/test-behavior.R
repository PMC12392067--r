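# Trial classification and the two SSRT estimators.

make_disp <- function(x, fs = 1000, t0 = 0)
  make_signal(x, fs = fs, t0_ms = t0, channel = "displacement")

test_that("classification follows the home-pad / target / frame rules", {
  sp <- fast_synth()  # home halfwidth 40, target at 500 +/- 40
  mk_trial <- function(type) data.frame(
    trial_id = 1L, block = 1L, trial_type = type, ssd_ms = 200,
    tms_time_ms = NA_real_, go_onset_ms = 0, response = "none",
    rt_ms = NA_real_, total_rt_ms = NA_real_, outcome_label = "correct_go",
    stringsAsFactors = FALSE)
  # flat displacement on a stop trial: early stop
  cont <- list(trial_1 = list(displacement = make_disp(numeric(1500))))
  expect_equal(classify_trials(mk_trial("stop"), cont, sp)$outcome_label,
               "early_stop")
  # stop-trial trace reaching the target: trigger failure
  reach <- c(seq(0, 520, length.out = 700), rep(520, 800))
  cont2 <- list(trial_1 = list(displacement = make_disp(reach)))
  got <- classify_trials(mk_trial("stop"), cont2, sp)
  expect_equal(got$outcome_label, "trigger_failure")
  expect_equal(got$rt_ms, which(reach > 40)[1] - 1)
  # exits home but never reaches target: late stop
  part <- c(seq(0, 200, length.out = 500), rep(200, 1000))
  cont3 <- list(trial_1 = list(displacement = make_disp(part)))
  expect_equal(classify_trials(mk_trial("stop"), cont3, sp)$outcome_label,
               "late_stop")
  # go trace crossing to the wrong side for 7 frames, then correcting
  wrong <- c(seq(0, -60, length.out = 60), rep(-60, 70),
             seq(-60, 520, length.out = 600), rep(520, 770))
  cont4 <- list(trial_1 = list(displacement = make_disp(wrong)))
  expect_equal(classify_trials(mk_trial("go"), cont4, sp)$outcome_label,
               "go_error_wrongdir")
  # the same excursion lasting only ~3 frames is a correct go
  brief <- c(seq(0, -60, length.out = 20),
             seq(-60, 520, length.out = 400), rep(520, 1080))
  cont5 <- list(trial_1 = list(displacement = make_disp(brief)))
  expect_equal(classify_trials(mk_trial("go"), cont5, sp)$outcome_label,
               "correct_go")
  # go trial that never reaches the target in 1.5 s: omission
  slow <- seq(0, 100, length.out = 1500)
  cont6 <- list(trial_1 = list(displacement = make_disp(slow)))
  expect_equal(classify_trials(mk_trial("go"), cont6, sp)$outcome_label,
               "go_omission")
  # a stop trial without a trace is an error
  expect_error(classify_trials(mk_trial("stop"), list(), sp), "missing")
})

test_that("integration SSRT follows the rank rule with omission replacement", {
  est <- integration_ssrt(c(300, 350, 400, 450, 500), 0.4, 150)
  expect_equal(est$rank, 2)
  expect_equal(est$ssrt_rm_ms, 200)
  # omissions enter at the maximum observed RT
  est2 <- integration_ssrt(c(300, 350, 400, NA, NA), 0.9, 100)
  expect_equal(est2$nth_rt_ms, 400)
  # p_respond near 1: max RT minus mean SSD
  est3 <- integration_ssrt(c(300, 350, 400, 450, 500), 1 - 1e-9, 150)
  expect_equal(est3$ssrt_rm_ms, 500 - 150)
  # degenerate probabilities are flagged undefined
  expect_warning(out <- integration_ssrt(c(300, 400), 1, 100), "undefined")
  expect_true(is.na(out$ssrt_rm_ms))
  expect_warning(integration_ssrt(c(300, 400), 0, 100), "undefined")
})

test_that("integration SSRT recovers the generator's mean stop latency", {
  rp <- exp1_race_params(n_blocks = 105)  # ~10,000 trials
  sim <- simulate_experiment(rp, fast_synth(), seed = 5, tms = FALSE)
  tt <- sim$trials
  is_stop <- tt$trial_type == "stop"
  p_resp <- mean(tt$outcome_label[is_stop] != "early_stop")
  go_set <- tt$trial_type == "go"
  rts <- ifelse(tt$outcome_label[go_set] == "go_omission", NA,
                tt$rt_ms[go_set])
  est <- integration_ssrt(rts, p_resp, mean(tt$ssd_ms[is_stop]))
  expect_lt(abs(est$ssrt_rm_ms - true_mean_stop_latency(rp)), 10)
})

test_that("kinematic SSRT finds the logistic inflection exactly", {
  fs <- 1000
  t <- seq(0, 1000, by = 1000 / fs)
  for (Tmid in c(300, 457, 650)) {
    x <- 1 / (1 + exp(-(t - Tmid) / 40))
    est <- kinematic_ssrt(list(make_disp(x)), stop_times_ms = 0)
    expect_equal(est$ssrt_k_ms, Tmid, tolerance = 1.01 * 1000 / fs)
  }
  # flat trace: excluded with a warning
  expect_warning(out <- kinematic_ssrt(list(make_disp(rep(0, 500))), 0),
                 "flat")
  expect_true(is.na(out$ssrt_k_ms))
})

test_that("trigger-failure rate recovers the generative probability", {
  tt <- data.frame(trial_type = rep("stop", 288),
                   outcome_label = rep("early_stop", 288))
  expect_equal(trigger_failure_rate(tt), 0)
  tt$outcome_label[] <- "trigger_failure"
  expect_equal(trigger_failure_rate(tt), 1)
  rp <- race_params(p_trigger_failure = 0.05, p_stop_trial = 0.5,
                    n_blocks = 209, trials_per_block = 96)
  sim <- simulate_experiment(rp, fast_synth(), seed = 23, tms = FALSE)
  est <- trigger_failure_rate(sim$trials)
  expect_lt(abs(est - 0.05), 0.01)
})

test_that("signal-respond RTs are faster than go RTs, as the race predicts", {
  worse <- 0
  for (s in 1:20) {
    sim <- simulate_experiment(race_params(), fast_synth(), seed = 100 + s,
                               tms = FALSE)
    tt <- sim$trials
    lr <- mean(tt$rt_ms[tt$outcome_label == "late_stop"], na.rm = TRUE)
    gr <- mean(tt$rt_ms[tt$outcome_label == "correct_go"], na.rm = TRUE)
    if (!(lr < gr)) worse <- worse + 1
  }
  expect_lte(worse, 1)
})
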