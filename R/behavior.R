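# Trial classification, RT metrics, and the two stopping-latency estimators.

#' Classify trials from cursor displacement traces
#'
#' Applies the operational rules of the reaching task. A response is any
#' excursion of the cursor beyond the home-pad half-width; target entry is
#' displacement within the target half-width of the target distance.
#' Stop trials: `early_stop` (never exits the home pad), `late_stop` (exits
#' but never reaches the target), `trigger_failure` (reaches the target).
#' Go trials: `go_error_wrongdir` when the cursor sits on the wrong side of
#' the screen midpoint for at least six consecutive display frames,
#' `go_omission` when the target is not reached within the 1.5 s timeout,
#' else `correct_go`. Displacement is signed, positive toward the cued
#' target.
#'
#' @param trials trial table.
#' @param container signal container holding a `displacement` channel per
#'   trial.
#' @param synth a [synth_params()] object supplying the geometry
#'   (`home_halfwidth_px`, `target_distance_px`, `target_halfwidth_px`,
#'   `frame_hz`).
#' @param timeout_ms response deadline (ms after the go signal).
#' @param min_frames_wrong consecutive wrong-side frames defining a
#'   wrong-direction error.
#' @return Data frame `trial_id`, `outcome_label`, `rt_ms` (home-pad exit),
#'   `total_rt_ms` (target entry).
#' @export
classify_trials <- function(trials, container, synth = synth_params(),
                            timeout_ms = 1500, min_frames_wrong = 6) {
  h <- synth$home_halfwidth_px
  tgt_lo <- synth$target_distance_px - synth$target_halfwidth_px
  out <- data.frame(trial_id = trials$trial_id,
                    outcome_label = NA_character_,
                    rt_ms = NA_real_, total_rt_ms = NA_real_,
                    stringsAsFactors = FALSE)
  for (k in seq_len(nrow(trials))) {
    key <- paste0("trial_", trials$trial_id[k])
    sig <- container[[key]]$displacement
    if (is.null(sig)) {
      if (trials$trial_type[k] == "go") {
        out$outcome_label[k] <- "go_omission"
        next
      }
      stop("missing displacement trace for trial ", trials$trial_id[k])
    }
    t <- index_to_ms(seq_along(sig$samples), sig$fs, sig$t0_ms)
    keep <- t >= 0 & t <= timeout_ms
    x <- sig$samples[keep]
    tt <- t[keep]
    i_exit <- which(abs(x) > h)[1]
    i_tgt <- which(x >= tgt_lo)[1]
    rt <- if (!is.na(i_exit)) tt[i_exit] else NA_real_
    total <- if (!is.na(i_tgt)) tt[i_tgt] else NA_real_
    if (trials$trial_type[k] == "stop") {
      out$outcome_label[k] <-
        if (is.na(rt)) "early_stop"
        else if (!is.na(total)) "trigger_failure"
        else "late_stop"
    } else {
      # wrong-direction rule, evaluated at display frames with a small
      # dead band around the midpoint
      fr <- seq(0, timeout_ms, by = 1000 / synth$frame_hz)
      xf <- stats::approx(tt, x, xout = fr, rule = 2)$y
      wrong <- xf < -h / 4
      runs <- run_ending_at(wrong)
      out$outcome_label[k] <-
        if (any(runs >= min_frames_wrong)) "go_error_wrongdir"
        else if (is.na(total)) "go_omission"
        else "correct_go"
    }
    out$rt_ms[k] <- rt
    out$total_rt_ms[k] <- total
  }
  out
}

#' Race-model (integration) estimate of the stop-signal reaction time
#'
#' Integration method with replacement of omissions: omitted go trials enter
#' the go RT distribution at the maximum observed RT; the RTs are sorted
#' ascending; the rank is `ceiling(p_respond * n)` (1-based); SSRT is that
#' quantile minus the mean SSD.
#'
#' @param go_rts numeric vector of go-trial RTs (ms), `NA` for omissions.
#' @param p_respond probability of responding given a stop signal, strictly
#'   between 0 and 1 (degenerate values flag the estimate as undefined).
#' @param mean_ssd mean stop-signal delay (ms).
#' @return List with `ssrt_rm_ms`, `nth_rt_ms`, `rank`, `n_go`,
#'   `p_respond`, `mean_ssd_ms`. `ssrt_rm_ms` is `NA` (with a warning) when
#'   `p_respond` is 0 or 1.
#' @examples
#' integration_ssrt(c(300, 350, 400, 450, 500), 0.4, 150)$ssrt_rm_ms  # 200
#' @export
integration_ssrt <- function(go_rts, p_respond, mean_ssd) {
  if (length(go_rts) < 1 || all(is.na(go_rts)))
    stop("need at least one go RT")
  if (!is.finite(p_respond) || p_respond <= 0 || p_respond >= 1) {
    warning("p_respond of ", p_respond,
            ": integration estimator undefined")
    return(list(ssrt_rm_ms = NA_real_, nth_rt_ms = NA_real_,
                rank = NA_integer_, n_go = length(go_rts),
                p_respond = p_respond, mean_ssd_ms = mean_ssd))
  }
  rts <- go_rts
  rts[is.na(rts)] <- max(rts, na.rm = TRUE)
  rts <- sort(rts)
  n <- length(rts)
  r <- min(max(ceiling(p_respond * n), 1L), n)
  list(ssrt_rm_ms = rts[r] - mean_ssd, nth_rt_ms = rts[r], rank = r,
       n_go = n, p_respond = p_respond, mean_ssd_ms = mean_ssd)
}

# Central-difference velocity with a centred moving-average smoother.
trace_velocity <- function(sig, smooth_ms = 20) {
  x <- sig$samples
  n <- length(x)
  dt_s <- 1 / sig$fs
  v <- c(NA, (x[3:n] - x[1:(n - 2)]) / (2 * dt_s), NA)
  v[1] <- v[2]; v[n] <- v[n - 1]
  w <- max(1L, round(smooth_ms * sig$fs / 1000))
  half <- w %/% 2L
  cs <- c(0, cumsum(v))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Kinematic estimate of the stop-signal reaction time
#'
#' Estimates per-trial stopping times on late stop trials as the time of
#' peak resultant cursor velocity relative to the stop signal (velocity by
#' central finite differences, smoothed with a 20 ms moving average), then
#' averages over trials after the 1.5 x IQR timing-outlier exclusion.
#'
#' @param displacements list of displacement sampled-signals (late stop
#'   trials).
#' @param stop_times_ms stop-signal times (ms relative to go), one per
#'   trial.
#' @param smooth_ms velocity smoothing window (ms).
#' @param min_peak_vel minimum peak velocity (units/s) below which a trace
#'   is treated as flat and excluded with a warning.
#' @return List with `ssrt_k_ms` (participant estimate), `per_trial_ms`
#'   (all per-trial values, `NA` where flat), and `included` (logical mask
#'   after outlier exclusion).
#' @export
kinematic_ssrt <- function(displacements, stop_times_ms, smooth_ms = 20,
                           min_peak_vel = 1e-6) {
  stopifnot(length(displacements) >= 1,
            length(displacements) == length(stop_times_ms))
  per <- rep(NA_real_, length(displacements))
  for (k in seq_along(displacements)) {
    sig <- displacements[[k]]
    v <- trace_velocity(sig, smooth_ms)
    if (max(v, na.rm = TRUE) < min_peak_vel) {
      warning("flat displacement trace excluded (trial ", k, ")")
      next
    }
    t <- index_to_ms(seq_along(v), sig$fs, sig$t0_ms)
    per[k] <- t[which.max(v)] - stop_times_ms[k]
  }
  keep <- !is.na(per) & !exclude_timing_outliers(per)
  list(ssrt_k_ms = if (any(keep)) mean(per[keep]) else NA_real_,
       per_trial_ms = per, included = keep)
}

#' Trigger-failure rate
#'
#' Proportion of stop trials in which the movement was never interrupted
#' before reaching the target (the stop process was not triggered).
#'
#' @param trials trial table with `outcome_label`.
#' @return Proportion in `[0, 1]`.
#' @export
trigger_failure_rate <- function(trials) {
  s <- trials$trial_type == "stop"
  if (!any(s)) return(NA_real_)
  mean(trials$outcome_label[s] == "trigger_failure")
}

#' Participant-level behavioural summary
#'
#' Computes the stop-signal performance indices for one participant's trial
#' table (and optionally signal container, for the kinematic SSRT): mean go
#' RT and total response time, mean late-stop RT, mean SSD, probability of
#' stopping, integration SSRT, kinematic SSRT, trigger-failure and go-error
#' rates.
#'
#' @param trials trial table (classified).
#' @param container optional signal container with displacement traces for
#'   late stop trials (enables `ssrt_k_ms`).
#' @param include_choice_errors include wrong-direction go RTs in the
#'   integration go-RT distribution (they count as responses; their RTs are
#'   excluded from timing means).
#' @return One-row data frame of the summary indices.
#' @export
behavior_summary <- function(trials, container = NULL,
                             include_choice_errors = TRUE) {
  is_go <- trials$trial_type == "go"
  is_stop <- !is_go
  correct_go <- trials$outcome_label == "correct_go"
  wrongdir <- trials$outcome_label == "go_error_wrongdir"
  omission <- trials$outcome_label == "go_omission"
  late <- trials$outcome_label == "late_stop"
  tf <- trials$outcome_label == "trigger_failure"

  go_set <- correct_go | omission | (wrongdir & include_choice_errors)
  go_rts <- trials$rt_ms[go_set]
  p_respond <- mean(!trials$outcome_label[is_stop] %in% "early_stop")
  mean_ssd <- mean(trials$ssd_ms[is_stop])
  est <- if (p_respond > 0 && p_respond < 1)
    integration_ssrt(go_rts, p_respond, mean_ssd)
  else list(ssrt_rm_ms = NA_real_)

  ssrt_k <- NA_real_
  if (!is.null(container) && any(late)) {
    ids <- trials$trial_id[late]
    ids <- ids[paste0("trial_", ids) %in% names(container)]
    if (length(ids) > 0) {
      disp <- lapply(ids, function(id) container[[paste0("trial_", id)]]$displacement)
      stops <- trials$ssd_ms[match(ids, trials$trial_id)]
      ssrt_k <- kinematic_ssrt(disp, stops)$ssrt_k_ms
    }
  }

  data.frame(
    n_trials = nrow(trials),
    go_rt_ms = mean(trials$rt_ms[correct_go], na.rm = TRUE),
    go_total_rt_ms = mean(trials$total_rt_ms[correct_go], na.rm = TRUE),
    late_stop_rt_ms = mean(trials$rt_ms[late], na.rm = TRUE),
    mean_ssd_ms = mean_ssd,
    p_stop = mean(trials$outcome_label[is_stop] == "early_stop"),
    ssrt_rm_ms = est$ssrt_rm_ms,
    ssrt_k_ms = ssrt_k,
    trigger_failure_pct = 100 * mean(tf[is_stop]),
    go_error_pct = 100 * mean((wrongdir | omission)[is_go]))
}
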