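# EMG preprocessing and burst detection.

#' Remove the TMS stimulus artifact by linear interpolation
#'
#' Replaces the samples from `artifact_pre_ms` before to `artifact_post_ms`
#' after the TMS pulse with a straight line between the boundary samples;
#' all other samples are untouched.
#'
#' @param signal sampled-signal list (`channel`, `fs`, `t0_ms`, `samples`).
#' @param tms_time_ms pulse time (ms relative to the go signal); the window
#'   must lie inside the recorded span.
#' @param pre_ms,post_ms window half-widths (ms); defaults 1 and 1.5.
#' @return The signal with the artifact window interpolated.
#' @export
interpolate_tms_artifact <- function(signal, tms_time_ms, pre_ms = 1,
                                     post_ms = 1.5) {
  n <- length(signal$samples)
  t <- index_to_ms(seq_len(n), signal$fs, signal$t0_ms)
  i0 <- which(t >= tms_time_ms - pre_ms)[1]
  i1 <- utils::tail(which(t <= tms_time_ms + post_ms), 1)
  if (is.na(i0) || length(i1) == 0 || i0 <= 1 || i1 >= n)
    stop("artifact window lies outside the recorded span")
  if (i1 >= i0) {
    a <- signal$samples[i0 - 1L]
    b <- signal$samples[i1 + 1L]
    k <- seq.int(i0, i1)
    signal$samples[k] <- a + (b - a) * (k - (i0 - 1L)) / (i1 + 1L - (i0 - 1L))
  }
  signal
}

# Second-order Butterworth band-pass plus band-stop, zero-phase by default.
# The upper band edge is capped just below Nyquist.
filter_emg <- function(signal, params = envelope_params()) {
  fs <- signal$fs
  nyq <- fs / 2
  hi <- min(params$bp_high, 0.99 * nyq)
  if (params$bp_low >= hi) stop("band-pass corners invalid for fs = ", fs)
  bp <- signal::butter(params$bp_order, c(params$bp_low, hi) / nyq,
                       type = "pass")
  bs <- signal::butter(params$bp_order, pmin(params$bs_band / nyq, 0.99),
                       type = "stop")
  apply_filt <- function(f, x) {
    if (params$zero_phase) signal::filtfilt(f, x)
    else as.numeric(signal::filter(f, x))
  }
  signal$samples <- apply_filt(bs, apply_filt(bp, signal$samples))
  signal
}

#' Full-wave rectified RMS envelope
#'
#' Rectifies the signal and computes the root mean square over a centred
#' window, truncated (shrinking) at the signal edges so no data are
#' invented. Sampling rate and time origin are preserved.
#'
#' @param signal sampled-signal list (band-pass filtered input).
#' @param params an [envelope_params()] object (uses `rms_window_ms`).
#' @return The envelope as a sampled-signal list.
#' @export
rms_envelope <- function(signal, params = envelope_params()) {
  x <- abs(signal$samples)
  n <- length(x)
  w <- max(1L, round(params$rms_window_ms * signal$fs / 1000))
  if (w > n) stop("RMS window longer than the signal")
  half <- w %/% 2L
  cs <- c(0, cumsum(x^2))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  signal$samples <- sqrt((cs[hi + 1L] - cs[lo]) / (hi - lo + 1L))
  signal
}

#' Preprocess one EMG channel to its RMS envelope
#'
#' Applies the full chain: TMS artifact interpolation (when a pulse time is
#' given), Butterworth band-pass, band-stop for mains hum, full-wave
#' rectification and centred-window RMS.
#'
#' @inheritParams rms_envelope
#' @param tms_time_ms TMS pulse time (ms relative to go) or `NA`.
#' @return The envelope as a sampled-signal list.
#' @export
preprocess_emg <- function(signal, params = envelope_params(),
                           tms_time_ms = NA) {
  if (!is.na(tms_time_ms))
    signal <- interpolate_tms_artifact(signal, tms_time_ms,
                                       params$artifact_pre_ms,
                                       params$artifact_post_ms)
  rms_envelope(filter_emg(signal, params), params)
}

# Run length of consecutive TRUEs ending at each index (vectorized).
run_ending_at <- function(flag) {
  n <- length(flag)
  idx <- seq_len(n)
  last_false <- cummax(ifelse(flag, 0L, idx))
  as.integer(ifelse(flag, idx - last_false, 0L))
}

#' Detect EMG bursts by peak thresholding and dwell backtracking
#'
#' Candidate peaks are local envelope maxima at or above `peak_frac` times
#' the go-trial reference peak (plateaus resolve to their earliest sample).
#' From each peak the onset is found by walking backward to the first run of
#' at least `min_dwell_ms` consecutive samples below `edge_frac` times the
#' burst's own peak (or the go reference, per `edge_reference`); the onset
#' is the first sample after that run. The offset is found symmetrically
#' forward. Candidates whose intervals overlap are merged into one burst
#' keeping the largest peak: candidates are resolved strongest first
#' (earliest on ties), each burst takes the dominant candidate's interval,
#' weaker candidates falling inside it are absorbed, and any remaining
#' overlapping intervals are dropped in favour of the larger peak. Gaps
#' shorter than the dwell do not split a burst. If no sub-threshold dwell
#' exists before (after) a peak, the onset (offset) clamps to the signal
#' edge.
#'
#' @param envelope sampled-signal list (RMS envelope).
#' @param go_reference_peak positive reference amplitude: the mean peak
#'   envelope over correct go trials.
#' @param params a [burst_params()] object.
#' @return Data frame with one row per burst, in time order: `onset_ms`,
#'   `peak_ms`, `offset_ms`, `peak_amp`, `peak_amp_norm` (fraction of the
#'   reference). Zero rows when nothing is suprathreshold.
#' @export
detect_bursts <- function(envelope, go_reference_peak,
                          params = burst_params()) {
  stopifnot(is.numeric(go_reference_peak), go_reference_peak > 0)
  env <- envelope$samples
  n <- length(env)
  fs <- envelope$fs
  dwell <- max(1L, round(params$min_dwell_ms * fs / 1000))
  th_peak <- params$peak_frac * go_reference_peak

  left <- c(-Inf, env[-n])
  right <- c(env[-1], -Inf)
  cand <- which(env >= th_peak & env > left & env >= right)
  if (length(cand) == 0)
    return(data.frame(onset_ms = numeric(0), peak_ms = numeric(0),
                      offset_ms = numeric(0), peak_amp = numeric(0),
                      peak_amp_norm = numeric(0)))

  interval_of <- function(p) {
    edge_base <- if (params$edge_reference == "burst_peak") env[p]
                 else go_reference_peak
    below <- env < params$edge_frac * edge_base
    r_end <- run_ending_at(below)
    ok_back <- which(r_end[seq_len(max(p - 1L, 0L))] >= dwell)
    onset <- if (length(ok_back) > 0) max(ok_back) + 1L else 1L
    r_start <- rev(run_ending_at(rev(below)))
    idx_fwd <- if (p < n) seq.int(p + 1L, n) else integer(0)
    ok_fwd <- idx_fwd[r_start[idx_fwd] >= dwell]
    offset <- if (length(ok_fwd) > 0) min(ok_fwd) - 1L else n
    c(onset, offset)
  }

  # strongest candidate first (earliest on ties); weaker candidates inside
  # an accepted interval belong to that burst
  ord <- cand[order(-env[cand], cand)]
  taken <- rep(FALSE, length(ord))
  bursts <- list()
  for (k in seq_along(ord)) {
    if (taken[k]) next
    p <- ord[k]
    iv <- interval_of(p)
    taken[ord >= iv[1] & ord <= iv[2]] <- TRUE
    bursts[[length(bursts) + 1L]] <- c(iv[1], iv[2], p)
  }
  m <- do.call(rbind, bursts)
  # drop any residual overlapping interval in favour of the larger peak
  if (nrow(m) > 1) {
    m <- m[order(m[, 1], m[, 3]), , drop = FALSE]
    keep <- rep(TRUE, nrow(m))
    last <- 1L
    for (k in 2L:nrow(m)) {
      if (m[k, 1] <= m[last, 2]) {
        if (env[m[k, 3]] > env[m[last, 3]]) keep[last] <- FALSE else keep[k] <- FALSE
        if (keep[k]) last <- k
      } else last <- k
    }
    m <- m[keep, , drop = FALSE]
  }
  m <- m[order(m[, 1]), , drop = FALSE]
  data.frame(
    onset_ms = index_to_ms(m[, 1], fs, envelope$t0_ms),
    peak_ms = index_to_ms(m[, 3], fs, envelope$t0_ms),
    offset_ms = index_to_ms(m[, 2], fs, envelope$t0_ms),
    peak_amp = env[m[, 3]],
    peak_amp_norm = env[m[, 3]] / go_reference_peak)
}

#' Normalize an envelope to a reference peak (% max)
#'
#' @param envelope sampled-signal list.
#' @param reference_peak positive reference amplitude (e.g. the mean peak
#'   agonist envelope over go trials, or the mean peak antagonist envelope
#'   over late stop trials).
#' @return The envelope expressed as percent of the reference.
#' @export
normalize_envelope <- function(envelope, reference_peak) {
  stopifnot(is.numeric(reference_peak), reference_peak > 0)
  envelope$samples <- 100 * envelope$samples / reference_peak
  envelope
}

#' Flag timing outliers by the 1.5 x IQR rule
#'
#' Flags values below `Q1 - 1.5 IQR` or above `Q3 + 1.5 IQR`, with quartiles
#' by the linear-interpolation convention (`stats::quantile` type 7). `NA`s
#' are never flagged.
#'
#' @param values numeric vector (at least 4 non-missing values; otherwise no
#'   flags, with a warning).
#' @return Logical vector, `TRUE` where a value is an outlier.
#' @export
exclude_timing_outliers <- function(values) {
  out <- rep(FALSE, length(values))
  ok <- !is.na(values)
  if (sum(ok) < 4) {
    if (sum(ok) > 0) warning("fewer than 4 values; no outliers flagged")
    return(out)
  }
  q <- stats::quantile(values[ok], c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- q[2] - q[1]
  out[ok] <- values[ok] < q[1] - 1.5 * iqr | values[ok] > q[2] + 1.5 * iqr
  out
}

#' Drop early antagonist bursts near the stop signal
#'
#' Antagonist bursts whose onset falls within `min_antagonist_onset_ms` of
#' the stop signal are slow postural rises rather than reactive braking and
#' are excluded; a trial with no antagonist burst is kept with missing
#' antagonist timing.
#'
#' @param bursts burst data frame (from [detect_bursts()]), onsets in ms
#'   relative to the go signal.
#' @param stop_time_ms stop-signal time (ms relative to the go signal).
#' @param params a [burst_params()] object.
#' @return The filtered burst data frame.
#' @export
exclude_early_antagonist <- function(bursts, stop_time_ms,
                                     params = burst_params()) {
  if (nrow(bursts) == 0) return(bursts)
  keep <- (bursts$onset_ms - stop_time_ms) >= params$min_antagonist_onset_ms
  bursts[keep, , drop = FALSE]
}

#' Mean peak envelope over a set of trials
#'
#' The burst-detection reference: the mean across trials of the per-trial
#' peak RMS envelope for one channel, restricted to trials with a given
#' outcome (correct go trials for the agonist reference; late stops for the
#' antagonist reference).
#'
#' @param container signal container (see [read_signals()]).
#' @param trials trial table.
#' @param channel channel name.
#' @param outcome outcome label(s) selecting the reference trials.
#' @param params an [envelope_params()] object.
#' @return Scalar reference peak (envelope units).
#' @export
reference_peak <- function(container, trials, channel = "agonist",
                           outcome = "correct_go",
                           params = envelope_params()) {
  ids <- trials$trial_id[trials$outcome_label %in% outcome]
  ids <- ids[paste0("trial_", ids) %in% names(container)]
  if (length(ids) == 0) stop("no reference trials present in the container")
  peaks <- vapply(ids, function(id) {
    i <- match(id, trials$trial_id)
    env <- preprocess_emg(container[[paste0("trial_", id)]][[channel]],
                          params, trials$tms_time_ms[i])
    max(env$samples)
  }, numeric(1))
  mean(peaks)
}

#' Per-trial EMG burst table for an experiment
#'
#' Runs the preprocessing chain and burst detector over the agonist and
#' antagonist channels of every requested trial. Agonist bursts are
#' referenced to the mean correct-go peak; antagonist bursts to the mean
#' late-stop antagonist peak. Antagonist bursts on stop trials starting
#' within the early-onset exclusion window of the stop signal are dropped.
#'
#' @param container signal container.
#' @param trials trial table.
#' @param env_params an [envelope_params()] object.
#' @param b_params a [burst_params()] object.
#' @param trial_ids trials to analyze (default: all in the container).
#' @param refs optional named list with precomputed `agonist` / `antagonist`
#'   reference peaks.
#' @return Data frame with columns `trial_id`, `channel`, `onset_ms`,
#'   `peak_ms`, `offset_ms`, `peak_amp`, `peak_amp_norm`.
#' @export
analyze_emg_bursts <- function(container, trials,
                               env_params = envelope_params(),
                               b_params = burst_params(),
                               trial_ids = NULL, refs = NULL) {
  if (is.null(trial_ids))
    trial_ids <- trials$trial_id[paste0("trial_", trials$trial_id) %in%
                                   names(container)]
  if (is.null(refs)) {
    refs <- list(
      agonist = reference_peak(container, trials, "agonist", "correct_go",
                               env_params),
      antagonist = reference_peak(container, trials, "antagonist",
                                  "late_stop", env_params))
  }
  rows <- vector("list", 2L * length(trial_ids))
  j <- 0L
  for (id in trial_ids) {
    i <- match(id, trials$trial_id)
    stop_time <- if (trials$trial_type[i] == "stop") trials$ssd_ms[i] else NA
    for (ch in c("agonist", "antagonist")) {
      env <- preprocess_emg(container[[paste0("trial_", id)]][[ch]],
                            env_params, trials$tms_time_ms[i])
      b <- detect_bursts(env, refs[[ch]], b_params)
      if (ch == "antagonist" && !is.na(stop_time))
        b <- exclude_early_antagonist(b, stop_time, b_params)
      if (nrow(b) > 0) {
        j <- j + 1L
        rows[[j]] <- cbind(data.frame(trial_id = id, channel = ch,
                                      stringsAsFactors = FALSE), b)
      }
    }
  }
  if (j == 0L)
    return(data.frame(trial_id = integer(0), channel = character(0),
                      onset_ms = numeric(0), peak_ms = numeric(0),
                      offset_ms = numeric(0), peak_amp = numeric(0),
                      peak_amp_norm = numeric(0)))
  out <- do.call(rbind, rows[seq_len(j)])
  rownames(out) <- NULL
  attr(out, "refs") <- refs
  out
}

#' Stop-aligned grand-average envelope
#'
#' Re-references each trial's RMS envelope to its stop signal, interpolates
#' onto a common grid and averages across trials. Event-aligned averages of
#' jittered bursts smear: the average's apparent offset exceeds the mean of
#' the per-trial offsets, which is why trial-level timing is analyzed and
#' averages are used for display only.
#'
#' @param container signal container.
#' @param trials trial table.
#' @param trial_ids stop trials to average.
#' @param channel channel name.
#' @param env_params an [envelope_params()] object.
#' @param span_ms grid span around the stop signal (ms).
#' @return Sampled-signal list with `t0_ms` relative to the stop signal.
#' @export
stop_aligned_average <- function(container, trials, trial_ids,
                                 channel = "agonist",
                                 env_params = envelope_params(),
                                 span_ms = c(-300, 600)) {
  fs <- container[[paste0("trial_", trial_ids[1])]][[channel]]$fs
  grid <- seq(span_ms[1], span_ms[2], by = 1000 / fs)
  acc <- numeric(length(grid))
  for (id in trial_ids) {
    i <- match(id, trials$trial_id)
    env <- preprocess_emg(container[[paste0("trial_", id)]][[channel]],
                          env_params, trials$tms_time_ms[i])
    t_rel <- index_to_ms(seq_along(env$samples), env$fs, env$t0_ms) -
      trials$ssd_ms[i]
    acc <- acc + stats::approx(t_rel, env$samples, xout = grid, rule = 2)$y
  }
  list(channel = channel, fs = fs, t0_ms = span_ms[1],
       samples = acc / length(trial_ids))
}
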