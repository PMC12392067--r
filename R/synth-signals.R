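# Forward model: latent trial truth -> sampled EMG, cursor kinematics, MEPs.

raised_cos <- function(u) 0.5 * (1 - cos(pi * pmin(pmax(u, 0), 1)))

# Phasic burst envelope: raised-cosine rise, exponential decay, optionally
# truncated by a forced raised-cosine decline starting at `decline_ms`.
phasic_envelope <- function(t, onset_ms, rise_ms, decay_ms, amp = 1,
                            decline_ms = NULL, fall_ms = 50) {
  env <- numeric(length(t))
  up <- t >= onset_ms & t < onset_ms + rise_ms
  env[up] <- amp * raised_cos((t[up] - onset_ms) / rise_ms)
  dn <- t >= onset_ms + rise_ms
  env[dn] <- amp * exp(-(t[dn] - onset_ms - rise_ms) / decay_ms)
  if (!is.null(decline_ms) && is.finite(decline_ms)) {
    v0 <- amp * if (decline_ms < onset_ms + rise_ms)
      raised_cos((decline_ms - onset_ms) / rise_ms)
    else exp(-(decline_ms - onset_ms - rise_ms) / decay_ms)
    cut <- t >= decline_ms
    env[cut] <- v0 * 0.5 * (1 + cos(pi * pmin((t[cut] - decline_ms) / fall_ms, 1)))
    env[t >= decline_ms + fall_ms] <- 0
  }
  env
}

# Sustained (tonic) envelope: raised-cosine rise then hold.
tonic_envelope <- function(t, onset_ms, rise_ms, amp) {
  env <- numeric(length(t))
  env[t >= onset_ms] <- amp * raised_cos((t[t >= onset_ms] - onset_ms) / rise_ms)
  env
}

# First-order damped kinematics with a static-friction regime. The cursor is
# clamped in the home pad until |drive| exceeds the static threshold;
# velocity then follows v' = (gain * drive - v) / tau while the drive is
# suprathreshold, and relaxes with the much shorter freeze constant once the
# drive drops below the static threshold (residual momentum settles instead
# of drifting indefinitely). On braked (stop) trials the cursor freezes once
# velocity reverses sign after the movement peak.
integrate_kinematics <- function(drive, fs, gain, tau_ms, static_threshold,
                                 brake = FALSE, freeze_tau_ms = 15,
                                 release_sign = c("positive", "both")) {
  release_sign <- match.arg(release_sign)
  n <- length(drive)
  dt_ms <- 1000 / fs
  # The cursor is released by the (agonist) thrust; a purely antagonist
  # (braking) drive never unclamps it. Deliberate wrong-direction starts
  # release on either sign.
  rel <- if (release_sign == "positive") which(drive > static_threshold)
         else which(abs(drive) > static_threshold)
  if (length(rel) == 0)
    return(list(x = numeric(n), v = numeric(n), release = NA_integer_))
  r <- rel[1]
  d <- drive
  d[seq_len(r - 1L)] <- 0
  fast <- abs(d) > static_threshold
  fast[seq_len(r - 1L)] <- FALSE
  a_fast <- exp(-dt_ms / tau_ms)
  a_slow <- exp(-dt_ms / freeze_tau_ms)
  # piecewise-constant damping: run the recursive filter segment by segment
  seg <- rle(fast)
  v <- numeric(n)
  pos <- 1L
  v_prev <- 0
  for (k in seq_along(seg$lengths)) {
    idx <- seq.int(pos, pos + seg$lengths[k] - 1L)
    a <- if (seg$values[k]) a_fast else a_slow
    v[idx] <- as.numeric(stats::filter((1 - a) * gain * d[idx], a,
                                       method = "recursive", init = v_prev))
    v_prev <- v[idx[length(idx)]]
    pos <- pos + seg$lengths[k]
  }
  if (brake) {
    ipk <- which.max(v)
    if (v[ipk] > 0) {
      post <- which(v[ipk:n] <= 0)
      if (length(post) > 0) {
        stopi <- ipk + post[1] - 1L
        v[stopi:n] <- 0
      }
    }
  }
  x <- cumsum(v) * dt_ms / 1000
  list(x = x, v = v, release = r)
}

.calib_cache <- new.env(parent = emptyenv())

#' Calibrate the forward kinematic model
#'
#' Solves the noiseless go-trial kinematics once for a given parameter set
#' to fix the structural constants that make the forward model and the
#' latent race mutually consistent: the drive gain that makes a full reach
#' land on the target centre; the lead of EMG onset over home-pad exit (so
#' a latent go finishing time equals the time the cursor leaves the home
#' pad); the movement duration from exit to target entry; the critical
#' truncation lag `critical_decline_ms` (the latest drive-decline start,
#' relative to EMG onset, for which the cursor still never leaves the home
#' pad); and the implied EMG-offset lead over the behavioural stop-process
#' completion time, `offset_lead_ms = emg_lead_ms - critical_decline_ms -
#' fall_ms`, which makes "command truncated early enough to stay inside the
#' home pad" coincide exactly with the race rule `ssd + stop_finish <
#' go_finish`.
#'
#' @param synth a [synth_params()] object.
#' @return A list with `gain` (px/s per unit drive), `emg_lead_ms`,
#'   `move_dur_ms`, `vel_peak_lag_ms` (velocity peak relative to EMG onset
#'   on a full reach), `critical_decline_ms` and `offset_lead_ms`.
#' @export
calibrate_kinematics <- function(synth) {
  key <- paste(synth$fs, synth$rise_ms, synth$decay_ms, synth$fall_ms,
               synth$kin_tau_ms, synth$kin_freeze_tau_ms,
               synth$kin_static_threshold, synth$target_distance_px,
               synth$target_halfwidth_px, synth$home_halfwidth_px,
               synth$emg_lead_floor_ms, sep = "|")
  if (!is.null(.calib_cache[[key]])) return(.calib_cache[[key]])
  fs <- synth$fs
  t <- seq(0, 1500, by = 1000 / fs)
  drive <- phasic_envelope(t, 0, synth$rise_ms, synth$decay_ms)
  k1 <- integrate_kinematics(drive, fs, gain = 1, synth$kin_tau_ms,
                             synth$kin_static_threshold,
                             freeze_tau_ms = synth$kin_freeze_tau_ms)
  xf <- k1$x[length(k1$x)]
  if (!is.finite(xf) || xf <= 0)
    stop("kinematic calibration failed: no displacement under unit gain")
  gain <- synth$target_distance_px / xf
  x <- gain * k1$x
  i_exit <- which(x > synth$home_halfwidth_px)[1]
  i_entry <- which(x >= synth$target_distance_px - synth$target_halfwidth_px)[1]
  if (is.na(i_exit) || is.na(i_entry))
    stop("kinematic calibration failed: calibrated reach misses the target")
  lead <- max(t[i_exit], synth$emg_lead_floor_ms)

  # Critical decline start: latest forced-truncation time (relative to EMG
  # onset) whose trajectory never exceeds the home-pad half-width. Monotone
  # in the truncation time, so bisection applies.
  peak_after <- function(td) {
    d <- phasic_envelope(t, 0, synth$rise_ms, synth$decay_ms,
                         decline_ms = td, fall_ms = synth$fall_ms)
    k <- integrate_kinematics(d, fs, gain, synth$kin_tau_ms,
                              synth$kin_static_threshold,
                              freeze_tau_ms = synth$kin_freeze_tau_ms)
    max(k$x)
  }
  lo <- 0; hi <- lead + synth$fall_ms
  for (it in 1:40) {
    mid <- (lo + hi) / 2
    if (peak_after(mid) <= synth$home_halfwidth_px) lo <- mid else hi <- mid
  }
  critical <- (lo + hi) / 2
  out <- list(gain = gain,
              emg_lead_ms = lead,
              move_dur_ms = t[i_entry] - t[i_exit],
              vel_peak_lag_ms = t[which.max(k1$v)],
              critical_decline_ms = critical,
              offset_lead_ms = lead - critical - synth$fall_ms)
  .calib_cache[[key]] <- out
  out
}

#' Synthesize the sampled signals of one trial
#'
#' Renders a trial's latent truth into three EMG channels (agonist,
#' antagonist, task-irrelevant) and a cursor displacement trace. The agonist
#' envelope rises at the planned onset, is forced into decline at the
#' cortical command offset plus the corticomuscular conduction delay, and
#' reaches baseline at the latent offset; on late stops a reactive
#' antagonist burst follows agonist offset; go and late-stop trials gain a
#' secondary tonic agonist bout whose amplitude grows with final
#' displacement (postural stabilization). Displacement follows first-order
#' damped integration of the net (agonist - antagonist) drive, clamped
#' inside the home pad until the drive beats a static threshold. EMG
#' carries multiplicative interference-pattern noise, additive baseline
#' noise and mains hum; with `noise_sd = 0` the deterministic envelopes are
#' returned (validation mode).
#'
#' @param truth_row one row of the truth table from [simulate_experiment()].
#' @param trial_row the matching row of the trial table.
#' @param synth a [synth_params()] object.
#' @param seed integer seed for the trial's noise draws.
#' @param calib kinematic calibration, normally from [calibrate_kinematics()].
#' @return Named list of sampled signals (`agonist`, `antagonist`,
#'   `task_irrelevant`, `displacement`), each a list with `channel`, `fs`,
#'   `t0_ms`, `samples`. The displacement element carries attributes
#'   `vel_peak_ms` (noiseless velocity-peak time, ms from go) and
#'   `final_disp_px`.
#' @export
synth_trial_signals <- function(truth_row, trial_row, synth, seed = 1,
                                calib = calibrate_kinematics(synth)) {
  stopifnot(inherits(synth, "synth_params"))
  if (isTRUE(truth_row$has_agonist_burst) &&
      !(truth_row$agonist_onset_ms < truth_row$agonist_peak_ms &&
        truth_row$agonist_peak_ms <= truth_row$agonist_offset_ms))
    stop("inconsistent trial truth: require onset < peak and peak <= offset")
  fs <- synth$fs
  t <- time_grid_ms(fs, synth$pre_ms, synth$post_ms)
  n <- length(t)
  outcome <- truth_row$outcome_label
  is_stop_trial <- outcome %in% c("early_stop", "late_stop", "trigger_failure")

  # --- deterministic envelopes -------------------------------------------
  ag_phasic <- numeric(n)
  wrong_burst <- numeric(n)
  if (isTRUE(truth_row$has_agonist_burst)) {
    onset <- truth_row$agonist_onset_ms
    decline <- if (!is.na(truth_row$agonist_offset_ms) &&
                   outcome %in% c("early_stop", "late_stop"))
      truth_row$agonist_offset_ms - synth$fall_ms else NULL
    if (isTRUE(truth_row$wrongdir)) {
      wrong_burst <- phasic_envelope(t, onset, 60, 60, amp = 0.5)
      onset <- onset + 150  # corrected response follows the wrong start
    }
    ag_phasic <- phasic_envelope(t, onset, synth$rise_ms, synth$decay_ms,
                                 amp = 1, decline_ms = decline,
                                 fall_ms = synth$fall_ms)
  }
  ant_env <- numeric(n)
  ant_reactive <- FALSE
  if (!is.na(truth_row$antagonist_onset_ms)) {
    if (isTRUE(truth_row$ant_slow)) {
      ant_env <- phasic_envelope(t, truth_row$antagonist_onset_ms, 200, 300,
                                 amp = truth_row$antagonist_amp)
    } else {
      ant_env <- phasic_envelope(t, truth_row$antagonist_onset_ms,
                                 synth$ant_rise_ms, synth$ant_fall_ms,
                                 amp = truth_row$antagonist_amp)
      ant_reactive <- is_stop_trial && outcome != "trigger_failure"
    }
  }

  # --- kinematics (phasic drives only; postural bout moves nothing) -------
  drive <- ag_phasic - wrong_burst -
    if (ant_reactive) synth$ant_drive_gain * ant_env else 0
  kin <- integrate_kinematics(drive, fs, calib$gain, synth$kin_tau_ms,
                              synth$kin_static_threshold,
                              brake = ant_reactive,
                              freeze_tau_ms = synth$kin_freeze_tau_ms,
                              release_sign = if (isTRUE(truth_row$wrongdir))
                                "both" else "positive")
  final_disp <- kin$x[n]
  vel_peak_ms <- if (any(kin$v > 0)) t[which.max(kin$v)] else NA_real_

  # --- secondary postural agonist bout scaling with final displacement ----
  disp_frac <- max(0, min(final_disp / synth$target_distance_px, 1.2))
  if (disp_frac > 0.05 && isTRUE(truth_row$has_agonist_burst)) {
    bout_on <- if (outcome == "late_stop" && !is.na(truth_row$agonist_offset_ms))
      truth_row$agonist_offset_ms + 120
    else truth_row$go_finish_ms + 0.6 * calib$move_dur_ms
    ag_env <- ag_phasic + tonic_envelope(t, bout_on, 150,
                                         synth$tonic_gain * disp_frac)
  } else ag_env <- ag_phasic

  # --- sampled signals ----------------------------------------------------
  sigs <- with_seed(seed, {
    mk_emg <- function(env) {
      if (synth$noise_sd == 0) return(env)
      carrier <- stats::rnorm(n)
      env * carrier + synth$noise_sd * stats::rnorm(n) +
        synth$mains_amp * sin(2 * pi * synth$mains_hz * t / 1000)
    }
    ti_active <- stats::runif(1) < synth$p_pretms_active
    ti <- if (synth$noise_sd == 0) numeric(n) else
      synth$noise_sd * stats::rnorm(n) +
      synth$mains_amp * sin(2 * pi * synth$mains_hz * t / 1000) +
      if (ti_active) 0.08 * stats::rnorm(n) else 0
    disp <- kin$x + if (synth$kin_noise_px > 0 && synth$noise_sd > 0)
      synth$kin_noise_px * stats::rnorm(n) else 0
    list(agonist = mk_emg(ag_env), antagonist = mk_emg(ant_env),
         task_irrelevant = ti, displacement = disp)
  })

  wrap <- function(ch, s) list(channel = ch, fs = fs, t0_ms = -synth$pre_ms,
                               samples = s)
  out <- list(agonist = wrap("agonist", sigs$agonist),
              antagonist = wrap("antagonist", sigs$antagonist),
              task_irrelevant = wrap("task_irrelevant", sigs$task_irrelevant),
              displacement = wrap("displacement", sigs$displacement))

  # --- TMS pulse: artifact on all EMG channels, MEP on the FDI channel ----
  if (!is.na(trial_row$tms_time_ms)) {
    tms_abs <- trial_row$tms_time_ms
    rel <- if (is_stop_trial) tms_abs - trial_row$ssd_ms else NA_real_
    for (ch in c("agonist", "antagonist"))
      out[[ch]]$samples <- add_tms_artifact(out[[ch]]$samples, t, tms_abs)
    out$task_irrelevant <- synth_mep(out$task_irrelevant, tms_abs, rel,
                                     truth_row, synth,
                                     seed = derive_seed(seed, 1L, 9L))
  }
  attr(out$displacement, "vel_peak_ms") <- vel_peak_ms
  attr(out$displacement, "final_disp_px") <- final_disp
  out
}

add_tms_artifact <- function(samples, t, tms_ms, amp = 5) {
  w <- t >= tms_ms & t <= tms_ms + 0.8
  samples[w] <- samples[w] + amp * sin(2 * pi * 2 * (t[w] - tms_ms))
  samples
}

#' Inject a TMS artifact and motor-evoked potential into a signal
#'
#' Adds a stimulus artifact at `tms_time_ms` and an MEP waveform whose
#' peak-to-peak amplitude is `mep_base_mv` times log-normal trial noise,
#' multiplied by `(1 - suppression_depth)` when the pulse falls inside the
#' trial's suppression window (times relative to the stop signal,
#' inclusive).
#'
#' @param signal a sampled-signal list (`channel`, `fs`, `t0_ms`, `samples`).
#' @param tms_time_ms pulse time, ms relative to the go signal; must lie
#'   within the recorded span.
#' @param tms_rel_stop_ms pulse time relative to the stop signal (`NA` on go
#'   trials, where no suppression applies).
#' @param truth_row truth-table row carrying `suppression_depth`,
#'   `supp_win_lo_ms`, `supp_win_hi_ms`.
#' @param synth a [synth_params()] object.
#' @param seed integer seed for the amplitude draw.
#' @return The signal with artifact and MEP added; attribute `true_p2p_mv`
#'   records the injected peak-to-peak amplitude.
#' @export
synth_mep <- function(signal, tms_time_ms, tms_rel_stop_ms, truth_row, synth,
                      seed = 1) {
  t <- index_to_ms(seq_along(signal$samples), signal$fs, signal$t0_ms)
  if (tms_time_ms < t[1] || tms_time_ms + 48 > t[length(t)])
    stop("TMS time outside the recorded span")
  suppressed <- !is.na(tms_rel_stop_ms) &&
    !is.na(truth_row$supp_win_lo_ms) &&
    tms_rel_stop_ms >= truth_row$supp_win_lo_ms &&
    tms_rel_stop_ms <= truth_row$supp_win_hi_ms
  amp <- with_seed(seed, draw_mep_amplitudes(1, synth, suppressed,
                                             depth = truth_row$suppression_depth))
  signal$samples <- add_tms_artifact(signal$samples, t, tms_time_ms)
  tau <- t - (tms_time_ms + synth$mep_latency_ms)
  w <- numeric(length(t))
  inw <- tau >= 0 & tau <= 25
  w[inw] <- sin(2 * pi * tau[inw] / 12.5) * exp(-tau[inw] / 8)
  p2p_unit <- max(w) - min(w)
  if (p2p_unit > 0) signal$samples <- signal$samples + (amp / p2p_unit) * w
  attr(signal, "true_p2p_mv") <- amp
  signal
}

#' Draw MEP peak-to-peak amplitudes from the generative model
#'
#' Log-normal trial-to-trial variability around `mep_base_mv`, scaled by
#' `(1 - depth)` for suppressed draws. The log-normal is mean-corrected so
#' that the expected unsuppressed amplitude equals `mep_base_mv`.
#'
#' @param n number of draws.
#' @param synth a [synth_params()] object.
#' @param suppressed logical scalar or vector of length `n`.
#' @param depth suppression depth; defaults to the generator's.
#' @return Numeric vector of amplitudes (mV).
#' @export
draw_mep_amplitudes <- function(n, synth, suppressed = FALSE,
                                depth = synth$suppression_depth) {
  s <- synth$mep_sigma_log
  base <- synth$mep_base_mv * stats::rlnorm(n, -s^2 / 2, s)
  base * (1 - depth * as.numeric(suppressed))
}

#' Synthesize signals for a set of trials
#'
#' Convenience wrapper: renders each requested trial of a simulated
#' experiment with [synth_trial_signals()], using per-trial seeds derived
#' from the master seed.
#'
#' @param sim output of [simulate_experiment()].
#' @param synth a [synth_params()] object (the one used for the simulation).
#' @param seed master seed.
#' @param trial_ids trials to render (default: all).
#' @return A signal container: named list `trial_<id>` of channel sets, with
#'   a `truth_kin` attribute (data frame of `trial_id`, `vel_peak_ms`,
#'   `final_disp_px`).
#' @export
synthesize_experiment <- function(sim, synth, seed = 1,
                                  trial_ids = sim$trials$trial_id) {
  calib <- attr(sim, "calibration") %||% calibrate_kinematics(synth)
  container <- vector("list", length(trial_ids))
  names(container) <- paste0("trial_", trial_ids)
  kin <- data.frame(trial_id = trial_ids, vel_peak_ms = NA_real_,
                    final_disp_px = NA_real_)
  for (k in seq_along(trial_ids)) {
    id <- trial_ids[k]
    i <- match(id, sim$trials$trial_id)
    sigs <- synth_trial_signals(sim$truth[i, ], sim$trials[i, ], synth,
                                seed = derive_seed(seed, id), calib = calib)
    kin$vel_peak_ms[k] <- attr(sigs$displacement, "vel_peak_ms")
    kin$final_disp_px[k] <- attr(sigs$displacement, "final_disp_px")
    container[[k]] <- sigs
  }
  attr(container, "truth_kin") <- kin
  container
}
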