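# MEP amplitude extraction, inclusion gating, suppression time course.

#' Peak-to-peak MEP amplitude
#'
#' Maximum minus minimum of the raw signal in the MEP window, 18 to 48 ms
#' after the TMS pulse.
#'
#' @param signal sampled-signal list (raw, band-passed, artifact-removed).
#' @param tms_time_ms pulse time (ms relative to the go signal); the window
#'   `[tms + 18, tms + 48]` must lie inside the recorded span.
#' @param window_ms MEP window relative to the pulse (ms).
#' @return Peak-to-peak amplitude (mV).
#' @export
measure_mep <- function(signal, tms_time_ms, window_ms = c(18, 48)) {
  t <- index_to_ms(seq_along(signal$samples), signal$fs, signal$t0_ms)
  lo <- tms_time_ms + window_ms[1]
  hi <- tms_time_ms + window_ms[2]
  if (lo < t[1] || hi > t[length(t)])
    stop("MEP window outside the recorded span")
  w <- signal$samples[t >= lo & t <= hi]
  max(w) - min(w)
}

#' Pre-TMS background-activity gate
#'
#' A measurement is included only if background EMG in the 100 ms before the
#' pulse is strictly below the threshold. Background activity is summarized
#' as the mean rectified amplitude (RMS available as an alternative).
#'
#' @param signal sampled-signal list.
#' @param tms_time_ms pulse time (ms relative to the go signal).
#' @param threshold_mv inclusion threshold (mV); at or above it the trial is
#'   excluded (strict `<`).
#' @param window_ms pre-pulse window length (ms).
#' @param summary `"mean_rectified"` (default) or `"rms"`.
#' @return Logical: include this measurement?
#' @export
gate_pre_tms <- function(signal, tms_time_ms, threshold_mv = 0.05,
                         window_ms = 100,
                         summary = c("mean_rectified", "rms")) {
  summary <- match.arg(summary)
  t <- index_to_ms(seq_along(signal$samples), signal$fs, signal$t0_ms)
  w <- signal$samples[t >= tms_time_ms - window_ms & t < tms_time_ms]
  if (length(w) == 0) stop("pre-TMS window outside the recorded span")
  activity <- if (summary == "mean_rectified") mean(abs(w))
              else sqrt(mean(w^2))
  activity < threshold_mv
}

#' Extract MEP measurements for every TMS trial
#'
#' For each trial with a TMS pulse: interpolates the stimulus artifact,
#' band-pass filters the task-irrelevant channel, applies the pre-TMS gate,
#' and measures the peak-to-peak amplitude. The TMS time point is expressed
#' relative to the stop signal (0 = go-signal baseline pulse on go trials).
#'
#' @param container signal container.
#' @param trials trial table.
#' @param env_params an [envelope_params()] object (filter settings).
#' @param channel channel carrying the MEPs.
#' @return Data frame `trial_id`, `trial_type` (outcome-level: `go`,
#'   `early_stop`, `late_stop`, `trigger_failure`, `go_error`),
#'   `tms_timepoint_ms`, `p2p_mv`, `included`.
#' @export
mep_measurements <- function(container, trials,
                             env_params = envelope_params(),
                             channel = "task_irrelevant") {
  ids <- trials$trial_id[!is.na(trials$tms_time_ms) &
                           paste0("trial_", trials$trial_id) %in%
                           names(container)]
  rows <- lapply(ids, function(id) {
    i <- match(id, trials$trial_id)
    sig <- container[[paste0("trial_", id)]][[channel]]
    tms <- trials$tms_time_ms[i]
    sig <- interpolate_tms_artifact(sig, tms, env_params$artifact_pre_ms,
                                    env_params$artifact_post_ms)
    sig <- filter_emg(sig, env_params)
    type <- switch(trials$outcome_label[i],
                   correct_go = "go",
                   go_error_wrongdir = "go_error",
                   go_omission = "go_error",
                   trials$outcome_label[i])
    tp <- if (trials$trial_type[i] == "stop") tms - trials$ssd_ms[i]
          else if (tms == 0) 0 else tms - trials$ssd_ms[i]
    tp <- round(tp * 10) / 10  # snap float jitter from fractional SSD steps
    data.frame(trial_id = id, trial_type = type, tms_timepoint_ms = tp,
               p2p_mv = measure_mep(sig, tms),
               included = gate_pre_tms(sig, tms),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Baseline-normalized MEP suppression time course
#'
#' Normalizes each included measurement to the subject's mean included
#' go-signal (baseline) amplitude and averages the ratios within each trial
#' type x TMS time point cell. Cells with fewer included trials than
#' `min_trials` are flagged missing.
#'
#' @param measurements data frame from [mep_measurements()] (one subject).
#' @param min_trials minimum included trials for a cell mean.
#' @param types trial types to tabulate.
#' @return Data frame `trial_type`, `tms_timepoint_ms`, `n_included`,
#'   `mean_ratio` (`NA` when flagged missing); attribute `baseline_mv`
#'   carries the subject baseline.
#' @export
suppression_timecourse <- function(measurements, min_trials = 1,
                                   types = c("go", "early_stop",
                                             "late_stop")) {
  inc <- measurements[measurements$included, , drop = FALSE]
  base <- inc$p2p_mv[inc$trial_type == "go" & inc$tms_timepoint_ms == 0]
  if (length(base) == 0) stop("no included baseline (go-signal) MEPs")
  baseline <- mean(base)
  tps <- sort(unique(inc$tms_timepoint_ms[inc$tms_timepoint_ms > 0]))
  grid <- expand.grid(trial_type = types, tms_timepoint_ms = tps,
                      stringsAsFactors = FALSE)
  grid$n_included <- NA_integer_
  grid$mean_ratio <- NA_real_
  for (k in seq_len(nrow(grid))) {
    sel <- inc$trial_type == grid$trial_type[k] &
      inc$tms_timepoint_ms == grid$tms_timepoint_ms[k]
    grid$n_included[k] <- sum(sel)
    if (sum(sel) >= min_trials)
      grid$mean_ratio[k] <- mean(inc$p2p_mv[sel]) / baseline
  }
  attr(grid, "baseline_mv") <- baseline
  grid
}

#' Corticomuscular conduction time
#'
#' The minimum MEP onset latency across a set of suprathreshold stimuli.
#'
#' @param onset_latencies_ms per-stimulus MEP onset latencies (ms).
#' @return Conduction time (ms).
#' @examples
#' conduction_time(c(24.1, 23.3, 25.0))  # 23.3
#' @export
conduction_time <- function(onset_latencies_ms) {
  lat <- onset_latencies_ms[!is.na(onset_latencies_ms)]
  if (length(lat) == 0) stop("no onset latencies supplied")
  min(lat)
}
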