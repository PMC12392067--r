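#' One staircase step of the stop-signal delay
#'
#' 1-up/1-down adaptive tracking: the SSD increases by `step` after a
#' successful stop and decreases by `step` after a failed stop, clamped at
#' zero. This drives the long-run probability of stopping toward 50%.
#'
#' @param ssd current stop-signal delay (ms), non-negative.
#' @param stop_succeeded logical; did the participant stop successfully?
#' @param step staircase step (ms), positive.
#' @return Updated SSD (ms).
#' @examples
#' update_ssd(200, TRUE, 50)   # 250
#' update_ssd(200, FALSE, 50)  # 150
#' update_ssd(0, FALSE, 50)    # clamped at 0
#' @export
update_ssd <- function(ssd, stop_succeeded, step) {
  if (!is.numeric(step) || length(step) != 1 || is.na(step) || step <= 0)
    stop("staircase step must be a single positive number")
  if (!is.numeric(ssd) || length(ssd) != 1 || is.na(ssd) || ssd < 0)
    stop("ssd must be a single non-negative number")
  max(0, ssd + if (isTRUE(stop_succeeded)) step else -step)
}

#' Simulate a stop-signal experiment from the independent race model
#'
#' Generates a full trial table and per-trial ground truth from an
#' independent horse race between an ex-Gaussian go process and a
#' zero-truncated-normal stop process, with a 1-up/1-down SSD staircase,
#' trigger failures, TMS scheduling (stop-trial time points plus go trials
#' yoked to the preceding stop trial's SSD), and the latent EMG burst and
#' MEP-suppression timings that [synth_trial_signals()] and [synth_mep()]
#' render into sampled signals.
#'
#' On a stop trial the stop wins iff the stop process was triggered and
#' `ssd + stop_finish < go_finish`; trigger-failure trials always produce a
#' full response. Go finishing times on stop trials are drawn from the same
#' go distribution as on go trials (context independence by construction).
#'
#' @param race a [race_params()] object.
#' @param synth a [synth_params()] object; supplies the timing constants that
#'   link the latent race to muscle-level events (conduction delay, envelope
#'   rise/fall, EMG-to-exit lead).
#' @param seed integer seed; identical seed and parameters give identical
#'   output.
#' @param tms logical; schedule TMS pulses (stop trials at the probe time
#'   points on five of six stop trials; half of go trials, split between a
#'   go-signal baseline pulse and pulses yoked to the preceding stop trial's
#'   SSD).
#' @return A list with elements `trials` (data frame, one row per trial with
#'   the trial-record schema) and `truth` (data frame of latent quantities:
#'   finishing times, trigger flag, cortical command offset, burst timings,
#'   suppression window). Attribute `calibration` carries the kinematic
#'   calibration used.
#' @export
simulate_experiment <- function(race, synth = synth_params(), seed = 1,
                                tms = TRUE) {
  stopifnot(inherits(race, "race_params"), inherits(synth, "synth_params"))
  calib <- calibrate_kinematics(synth)
  offset_lead <- if (is.na(synth$offset_lead_ms)) calib$offset_lead_ms
                 else synth$offset_lead_ms
  n_total <- race$n_blocks * race$trials_per_block
  out <- with_seed(seed, {
    n_stop_blk <- round(race$p_stop_trial * race$trials_per_block)
    is_stop <- unlist(lapply(seq_len(race$n_blocks), function(b) {
      sample(rep(c(TRUE, FALSE),
                 c(n_stop_blk, race$trials_per_block - n_stop_blk)))
    }))
    n_stop <- sum(is_stop)

    # Balanced TMS schedule: 5 of 6 stop trials probed, time points balanced.
    tp <- synth$tms_timepoints_ms
    stop_tp <- sample(rep_len(c(tp, NA_real_), n_stop))
    go_has_tms <- sample(rep_len(c(TRUE, FALSE), n_total - n_stop))
    go_is_baseline <- sample(rep_len(c(TRUE, FALSE), n_total - n_stop))
    go_tp <- sample(rep_len(tp, n_total - n_stop))

    go_finish <- rexgauss(n_total, race$go_mu, race$go_sigma, race$go_tau)
    go_finish <- pmax(go_finish, 50)
    stop_finish <- rep(NA_real_, n_total)
    triggered <- rep(NA, n_total)
    wrongdir <- !is_stop & stats::runif(n_total) < race$p_wrongdir
    omission <- !is_stop & !wrongdir & stats::runif(n_total) < race$p_omission
    sf_draw <- rtruncnorm0(n_total, race$stop_mu, race$stop_sigma)
    trig_draw <- stats::runif(n_total) >= race$p_trigger_failure
    ant_u <- stats::runif(n_total)
    ant_slow_u <- stats::runif(n_total)
    ant_amp_jit <- stats::rlnorm(n_total, -0.02, 0.2)
    slow_onset_jit <- stats::runif(n_total, 10, 45)

    ssd <- rep(NA_real_, n_total)
    outcome <- character(n_total)
    cur_ssd <- race$ssd_init
    last_stop_ssd <- race$ssd_init
    i_stop <- 0L
    i_go <- 0L
    tms_time <- rep(NA_real_, n_total)
    tms_tp_rel <- rep(NA_real_, n_total)

    for (i in seq_len(n_total)) {
      if (is_stop[i]) {
        i_stop <- i_stop + 1L
        ssd[i] <- cur_ssd
        triggered[i] <- trig_draw[i]
        stop_finish[i] <- sf_draw[i]
        stop_won <- triggered[i] && (ssd[i] + stop_finish[i]) < go_finish[i]
        outcome[i] <- if (!triggered[i]) "trigger_failure"
          else if (stop_won) "early_stop" else "late_stop"
        if (tms && !is.na(stop_tp[i_stop])) {
          tms_tp_rel[i] <- stop_tp[i_stop]
          tms_time[i] <- ssd[i] + stop_tp[i_stop]
        }
        last_stop_ssd <- ssd[i]
        cur_ssd <- update_ssd(cur_ssd, stop_won, race$ssd_step)
      } else {
        i_go <- i_go + 1L
        ssd[i] <- last_stop_ssd  # yoked SSD
        outcome[i] <- if (omission[i]) "go_omission"
          else if (wrongdir[i]) "go_error_wrongdir" else "correct_go"
        if (tms && go_has_tms[i_go]) {
          if (go_is_baseline[i_go]) {
            tms_tp_rel[i] <- 0
            tms_time[i] <- 0
          } else {
            tms_tp_rel[i] <- go_tp[i_go]
            tms_time[i] <- ssd[i] + go_tp[i_go]
          }
        }
      }
    }

    cue <- sample(c("left", "right"), n_total, replace = TRUE)

    truth <- build_trial_truth(
      seq_len(n_total), is_stop, go_finish, stop_finish, triggered,
      omission, wrongdir, ssd, outcome, synth, calib, offset_lead,
      ant_u, ant_slow_u, ant_amp_jit, slow_onset_jit)

    responds <- outcome %in% c("correct_go", "go_error_wrongdir",
                               "late_stop", "trigger_failure")
    reaches <- outcome %in% c("correct_go", "go_error_wrongdir",
                              "trigger_failure")
    rt <- ifelse(responds, go_finish, NA_real_)
    total_rt <- ifelse(reaches, go_finish + calib$move_dur_ms, NA_real_)
    response <- ifelse(!responds, "none",
                       ifelse(wrongdir,
                              ifelse(cue == "left", "right", "left"), cue))

    trials <- data.frame(
      trial_id = seq_len(n_total),
      block = rep(seq_len(race$n_blocks), each = race$trials_per_block),
      trial_type = ifelse(is_stop, "stop", "go"),
      ssd_ms = ssd,
      tms_time_ms = tms_time,
      go_onset_ms = 0,
      response = response,
      rt_ms = rt,
      total_rt_ms = total_rt,
      outcome_label = outcome,
      stringsAsFactors = FALSE)
    truth$tms_timepoint_ms <- tms_tp_rel
    list(trials = trials, truth = truth)
  })
  attr(out, "calibration") <- calib
  out
}

# Latent burst/suppression timings implied by the race outcome. All times in
# ms relative to the go signal unless suffixed _rel_stop.
build_trial_truth <- function(trial_id, is_stop, go_finish, stop_finish,
                              triggered, omission, wrongdir, ssd, outcome,
                              synth, calib, offset_lead,
                              ant_u, ant_slow_u, ant_amp_jit,
                              slow_onset_jit) {
  n <- length(trial_id)
  onset <- go_finish - calib$emg_lead_ms
  peak <- onset + synth$rise_ms
  offset <- peak + 3 * synth$decay_ms
  has_burst <- !omission
  cmd_off <- rep(NA_real_, n)
  ant_onset <- rep(NA_real_, n)
  ant_amp <- rep(NA_real_, n)
  ant_slow <- rep(FALSE, n)
  depth <- rep(0, n)
  win_lo <- rep(NA_real_, n)
  win_hi <- rep(NA_real_, n)

  stop_idx <- which(is_stop & triggered)
  for (i in stop_idx) {
    t_stop_abs <- ssd[i] + stop_finish[i]
    off_i <- t_stop_abs - offset_lead
    decline <- off_i - synth$fall_ms
    cmd_off[i] <- decline - synth$conduction_delay_ms - ssd[i]
    if (decline <= onset[i]) {
      has_burst[i] <- FALSE
      onset[i] <- peak[i] <- offset[i] <- NA_real_
    } else {
      peak[i] <- min(onset[i] + synth$rise_ms, decline)
      offset[i] <- off_i
    }
    early <- outcome[i] == "early_stop"
    p_ant <- if (early) synth$p_ant_early else synth$p_ant_late
    if (ant_u[i] < p_ant) {
      ant_onset[i] <- off_i + synth$ant_gap_ms
      base_amp <- if (early) synth$ant_amp_early else synth$ant_amp_late
      ant_amp[i] <- base_amp * ant_amp_jit[i]
    }
    if (ant_slow_u[i] < synth$p_ant_slow) {
      # slow postural antagonist rise shortly after the stop signal
      ant_slow[i] <- TRUE
      ant_onset[i] <- ssd[i] + slow_onset_jit[i]
      ant_amp[i] <- 0.3 * ant_amp_jit[i]
    }
    depth[i] <- synth$suppression_depth
    win <- if (early) synth$window_early_ms else synth$window_late_ms
    win_lo[i] <- win[1]
    win_hi[i] <- win[2]
  }
  # Weak, variably timed antagonist activity on a subset of go-like trials.
  go_like <- which(!is_stop | (is_stop & !triggered))
  pick <- go_like[ant_u[go_like] < synth$p_ant_go & !omission[go_like]]
  ant_onset[pick] <- go_finish[pick] + 60 + 80 * ant_slow_u[pick]
  ant_amp[pick] <- synth$ant_amp_go * ant_amp_jit[pick]

  data.frame(
    trial_id = trial_id,
    go_finish_ms = ifelse(omission, NA_real_, go_finish),
    stop_finish_ms = stop_finish,
    triggered = triggered,
    wrongdir = wrongdir,
    cmd_offset_ms = cmd_off,
    has_agonist_burst = has_burst,
    agonist_onset_ms = ifelse(has_burst, onset, NA_real_),
    agonist_peak_ms = ifelse(has_burst, peak, NA_real_),
    agonist_offset_ms = ifelse(has_burst, offset, NA_real_),
    antagonist_onset_ms = ant_onset,
    antagonist_amp = ant_amp,
    ant_slow = ant_slow,
    suppression_depth = depth,
    supp_win_lo_ms = win_lo,
    supp_win_hi_ms = win_hi,
    outcome_label = outcome,
    stringsAsFactors = FALSE)
}

#' Generator-truth mean stop latency
#'
#' Mean of the zero-truncated normal stop finishing-time distribution; the
#' quantity the integration SSRT estimator should recover.
#'
#' @param race a [race_params()] object.
#' @return Mean stop latency (ms).
#' @export
true_mean_stop_latency <- function(race) {
  truncnorm0_mean(race$stop_mu, race$stop_sigma)
}
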