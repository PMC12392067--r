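#' Race-model parameters for the synthetic stop-signal experiment
#'
#' Bundles the parameters of the independent horse-race generator: an
#' ex-Gaussian distribution of go finishing times, a zero-truncated normal
#' distribution of stop finishing times, a trigger-failure probability, and
#' the 1-up/1-down staircase that adapts the stop-signal delay (SSD).
#'
#' Defaults describe the whole-arm reaching task variant: go finishing times
#' with mean ~508 ms, stop latencies with mean ~264 ms, a 33.3 ms staircase
#' step and a 2.8% trigger-failure rate. Use [exp1_race_params()] for the
#' ballistic key-press variant (go mean ~430 ms, stop mean ~217 ms, 50 ms
#' steps).
#'
#' @param go_mu,go_sigma,go_tau ex-Gaussian parameters of the go finishing
#'   time (ms). The distribution mean is `go_mu + go_tau`.
#' @param stop_mu,stop_sigma normal parameters of the stop finishing time
#'   (ms), truncated at zero.
#' @param p_trigger_failure probability that the stop process is never
#'   triggered on a stop trial.
#' @param ssd_init initial SSD (ms); in practice titrated per participant so
#'   the staircase starts near its equilibrium.
#' @param ssd_step staircase step (ms): SSD increases by this after a
#'   successful stop and decreases by it after a failed stop.
#' @param n_blocks,trials_per_block experiment size.
#' @param p_stop_trial fraction of stop trials (exact per block).
#' @param p_wrongdir probability a go trial starts toward the wrong target.
#' @param p_omission probability a go trial produces no response at all.
#' @return An object of class `race_params` (a validated list).
#' @examples
#' rp <- race_params(n_blocks = 2, trials_per_block = 48)
#' rp$ssd_step
#' @export
race_params <- function(go_mu = 370, go_sigma = 50, go_tau = 138,
                        stop_mu = 264, stop_sigma = 30,
                        p_trigger_failure = 0.028,
                        ssd_init = 250, ssd_step = 100 / 3,
                        n_blocks = 12, trials_per_block = 96,
                        p_stop_trial = 0.25,
                        p_wrongdir = 0.059, p_omission = 0.004) {
  stopifnot(go_sigma > 0, go_tau > 0, stop_sigma > 0,
            ssd_init >= 0, ssd_step > 0,
            n_blocks >= 1, trials_per_block >= 1,
            p_stop_trial > 0, p_stop_trial < 1,
            p_wrongdir >= 0, p_wrongdir < 1, p_omission >= 0, p_omission < 1)
  if (p_trigger_failure < 0 || p_trigger_failure > 1)
    stop("p_trigger_failure must lie in [0, 1]")
  structure(list(go_mu = go_mu, go_sigma = go_sigma, go_tau = go_tau,
                 stop_mu = stop_mu, stop_sigma = stop_sigma,
                 p_trigger_failure = p_trigger_failure,
                 ssd_init = ssd_init, ssd_step = ssd_step,
                 n_blocks = n_blocks, trials_per_block = trials_per_block,
                 p_stop_trial = p_stop_trial,
                 p_wrongdir = p_wrongdir, p_omission = p_omission),
            class = "race_params")
}

#' @rdname race_params
#' @export
exp1_race_params <- function(go_mu = 330, go_sigma = 40, go_tau = 100,
                             stop_mu = 217, stop_sigma = 30,
                             p_trigger_failure = 0,
                             ssd_init = 190, ssd_step = 50, ...) {
  race_params(go_mu = go_mu, go_sigma = go_sigma, go_tau = go_tau,
              stop_mu = stop_mu, stop_sigma = stop_sigma,
              p_trigger_failure = p_trigger_failure,
              ssd_init = ssd_init, ssd_step = ssd_step, ...)
}

#' Signal-synthesis parameters for the forward model
#'
#' Parameters of the forward model that turns latent race/burst timings into
#' sampled EMG channels, a cursor displacement trace, and TMS-evoked
#' potentials. Times are milliseconds relative to the go signal; amplitudes
#' are millivolts for EMG/MEP channels and pixels for displacement.
#'
#' @param fs sampling rate of the EMG channels (Hz); 4000 for the reaching
#'   task, 1000 for the key-press task.
#' @param pre_ms,post_ms recorded span around the go signal (captured from
#'   `pre_ms` before it to `post_ms` after it).
#' @param conduction_delay_ms corticomuscular conduction delay between the
#'   cortical command and muscle-level EMG (9.6 ms for deltoid, 23.3 for
#'   intrinsic hand muscles).
#' @param rise_ms raised-cosine rise time of the agonist burst envelope.
#' @param decay_ms exponential decay constant of the unstopped burst.
#' @param fall_ms duration of the forced raised-cosine decline when the
#'   cortical command is cut by the stop process.
#' @param offset_lead_ms lead of the agonist EMG offset over the behavioural
#'   stop-process completion time on triggered stop trials. The default
#'   `NA` derives it from the kinematic calibration so that the trace-level
#'   outcome (cursor leaves the home pad or not) coincides with the latent
#'   race rule; see [calibrate_kinematics()].
#' @param emg_lead_floor_ms minimum allowed lead of EMG onset over home-pad
#'   exit (safety floor for the calibrated lead).
#' @param ant_rise_ms,ant_fall_ms,ant_gap_ms antagonist burst envelope rise
#'   and fall times and its onset gap after agonist offset.
#' @param ant_amp_late,ant_amp_early,ant_amp_go antagonist burst amplitudes
#'   (fractions of the late-stop reference).
#' @param p_ant_late,p_ant_early,p_ant_go probability an antagonist burst is
#'   present by trial type.
#' @param p_ant_slow probability of a slow early postural antagonist rise
#'   beginning right after the stop signal (the events the 50 ms exclusion
#'   rule removes).
#' @param tonic_gain amplitude of the secondary (postural) agonist bout per
#'   unit of final displacement (fraction of the phasic peak at full reach).
#' @param noise_sd baseline EMG noise standard deviation (mV).
#' @param mains_hz,mains_amp mains hum frequency (Hz) and amplitude (mV).
#' @param mep_base_mv median unsuppressed MEP peak-to-peak amplitude (mV).
#' @param mep_sigma_log log-normal dispersion of trial-to-trial MEP size.
#' @param mep_latency_ms MEP onset latency after the TMS pulse.
#' @param suppression_depth fractional MEP reduction inside the suppression
#'   window.
#' @param window_early_ms,window_late_ms suppression windows (ms after the
#'   stop signal, inclusive) for early-stop and late-stop trials.
#' @param p_pretms_active probability that background activity contaminates
#'   the task-irrelevant muscle before the TMS pulse (gate-exclusion cases).
#' @param tms_timepoints_ms TMS times probed after the stop signal.
#' @param home_halfwidth_px,target_distance_px,target_halfwidth_px task
#'   geometry: home-pad half-width, distance from home centre to target
#'   centre, and target half-width (px).
#' @param frame_hz display frame rate used by the wrong-direction rule.
#' @param kin_tau_ms first-order damping time constant of cursor velocity
#'   while the drive is above the static threshold. Long relative to the
#'   burst (inertial regime), so velocity peaks near the zero crossing of
#'   the net drive — the agonist-offset/antagonist-onset transition.
#' @param kin_freeze_tau_ms damping time constant once the drive falls below
#'   the static threshold (residual momentum settles quickly, as against
#'   static friction).
#' @param kin_static_threshold drive level (fraction of the go-trial drive
#'   peak) below which the cursor stays clamped inside the home pad.
#' @param ant_drive_gain weight of the antagonist drive in the net kinematic
#'   drive.
#' @param kin_noise_px measurement jitter added to the displacement trace.
#' @return An object of class `synth_params`.
#' @export
synth_params <- function(fs = 4000, pre_ms = 1000, post_ms = 1500,
                         conduction_delay_ms = 9.6,
                         rise_ms = 50, decay_ms = 120, fall_ms = 30,
                         offset_lead_ms = NA, emg_lead_floor_ms = 40,
                         ant_rise_ms = 40, ant_fall_ms = 120, ant_gap_ms = 10,
                         ant_amp_late = 1.0, ant_amp_early = 0.27,
                         ant_amp_go = 0.42,
                         p_ant_late = 0.93, p_ant_early = 0.47, p_ant_go = 0.57,
                         p_ant_slow = 0.08,
                         tonic_gain = 0.45,
                         noise_sd = 0.01, mains_hz = 50, mains_amp = 0.005,
                         mep_base_mv = 1.0, mep_sigma_log = 0.35,
                         mep_latency_ms = 20,
                         suppression_depth = 0.3,
                         window_early_ms = c(150, 300),
                         window_late_ms = c(150, 150),
                         p_pretms_active = 0.05,
                         tms_timepoints_ms = c(100, 150, 200, 250, 300),
                         home_halfwidth_px = 40, target_distance_px = 500,
                         target_halfwidth_px = 40,
                         frame_hz = 60,
                         kin_tau_ms = 400, kin_freeze_tau_ms = 15,
                         kin_static_threshold = 0.15,
                         ant_drive_gain = 1.2, kin_noise_px = 1) {
  stopifnot(fs > 0, conduction_delay_ms > 0, rise_ms > 0, decay_ms > 0,
            fall_ms > 0, noise_sd >= 0, mains_amp >= 0,
            mep_base_mv > 0, mep_sigma_log >= 0,
            suppression_depth >= 0, suppression_depth <= 1,
            length(window_early_ms) == 2, length(window_late_ms) == 2,
            home_halfwidth_px > 0, target_distance_px > home_halfwidth_px,
            kin_tau_ms > 0, frame_hz > 0)
  structure(as.list(environment()), class = "synth_params")
}

#' @rdname synth_params
#' @details `exp1_synth_params()` binds the key-press variant defaults:
#'   1 kHz sampling, 23.3 ms conduction delay, 60 Hz mains.
#' @export
exp1_synth_params <- function(fs = 1000, conduction_delay_ms = 23.3,
                              mains_hz = 60, ...) {
  synth_params(fs = fs, conduction_delay_ms = conduction_delay_ms,
               mains_hz = mains_hz, ...)
}

#' EMG envelope (preprocessing) parameters
#'
#' Filtering and smoothing constants for the EMG preprocessing chain:
#' second-order Butterworth band-pass, band-stop for mains hum, full-wave
#' rectification and a centred RMS window.
#'
#' @param bp_low,bp_high band-pass corner frequencies (Hz). `bp_high` is
#'   capped below the Nyquist frequency at filter time.
#' @param bp_order Butterworth order of each pass (applied forward and
#'   backward when `zero_phase`).
#' @param bs_band band-stop edges (Hz) bracketing the mains frequency:
#'   `c(58, 62)` for 60 Hz mains, `c(48, 52)` for 50 Hz.
#' @param rms_window_ms centred RMS window length (ms).
#' @param artifact_pre_ms,artifact_post_ms interpolation window around each
#'   TMS pulse (ms before / after).
#' @param zero_phase logical; forward-backward (zero-phase) filtering when
#'   TRUE, causal single-pass otherwise.
#' @return An object of class `envelope_params`.
#' @export
envelope_params <- function(bp_low = 10, bp_high = 2000, bp_order = 2,
                            bs_band = c(48, 52), rms_window_ms = 20,
                            artifact_pre_ms = 1, artifact_post_ms = 1.5,
                            zero_phase = TRUE) {
  stopifnot(bp_low > 0, bp_high > bp_low, bp_order >= 1,
            length(bs_band) == 2, bs_band[1] < bs_band[2],
            rms_window_ms > 0, artifact_pre_ms >= 0, artifact_post_ms >= 0)
  structure(list(bp_low = bp_low, bp_high = bp_high, bp_order = bp_order,
                 bs_band = bs_band, rms_window_ms = rms_window_ms,
                 artifact_pre_ms = artifact_pre_ms,
                 artifact_post_ms = artifact_post_ms,
                 zero_phase = zero_phase),
            class = "envelope_params")
}

#' Burst-detection parameters
#'
#' Thresholds for the peak/backtracking burst detector. Candidate peaks must
#' exceed `peak_frac` of the go-trial reference peak; onsets/offsets are
#' found by walking away from the peak until the envelope stays below
#' `edge_frac` of the burst peak for at least `min_dwell_ms`.
#'
#' @param peak_frac peak threshold as a fraction of the go-trial reference
#'   peak (0.10 key-press variant, 0.15 reaching variant).
#' @param edge_frac onset/offset threshold as a fraction of the burst's own
#'   peak (0.05 / 0.10); see `edge_reference`.
#' @param min_dwell_ms minimum sub-threshold dwell (ms).
#' @param min_antagonist_onset_ms antagonist bursts with onsets within this
#'   many ms of the stop signal are excluded as slow postural rises.
#' @param edge_reference `"burst_peak"` (default) scales `edge_frac` by each
#'   burst's own peak; `"go_reference"` scales it by the go-trial reference.
#' @return An object of class `burst_params`.
#' @export
burst_params <- function(peak_frac = 0.15, edge_frac = 0.10,
                         min_dwell_ms = 20, min_antagonist_onset_ms = 50,
                         edge_reference = c("burst_peak", "go_reference")) {
  edge_reference <- match.arg(edge_reference)
  stopifnot(edge_frac > 0, edge_frac < peak_frac, peak_frac <= 1,
            min_dwell_ms > 0, min_antagonist_onset_ms >= 0)
  structure(list(peak_frac = peak_frac, edge_frac = edge_frac,
                 min_dwell_ms = min_dwell_ms,
                 min_antagonist_onset_ms = min_antagonist_onset_ms,
                 edge_reference = edge_reference),
            class = "burst_params")
}

#' @export
print.race_params <- function(x, ...) {
  cat("Race-model parameters\n")
  cat(sprintf("  go finishing time: ex-Gaussian(mu=%g, sigma=%g, tau=%g), mean %g ms\n",
              x$go_mu, x$go_sigma, x$go_tau, x$go_mu + x$go_tau))
  cat(sprintf("  stop finishing time: truncN(mu=%g, sigma=%g) ms\n",
              x$stop_mu, x$stop_sigma))
  cat(sprintf("  trigger failures: %.1f%%; staircase step %.1f ms from SSD %g ms\n",
              100 * x$p_trigger_failure, x$ssd_step, x$ssd_init))
  cat(sprintf("  %d blocks x %d trials, %.0f%% stop trials\n",
              x$n_blocks, x$trials_per_block, 100 * x$p_stop_trial))
  invisible(x)
}
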