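# Orchestration: experiment profiles, per-subject analysis, end-to-end runs.

#' Build a run configuration for an experiment profile
#'
#' Binds the parameter defaults of the two task variants. Profile `exp1`
#' (ballistic key press): 1 kHz sampling, 50 ms staircase steps, burst
#' thresholds 10%/5%, 58-62 Hz band-stop, 23.3 ms conduction delay, band
#' pass 10-450 Hz (upper corner held below the 1 kHz Nyquist). Profile
#' `exp2` (whole-arm reaching): 4 kHz sampling, 33.3 ms steps, thresholds
#' 15%/10%, 48-52 Hz band-stop, 9.6 ms conduction delay, band pass
#' 10-2000 Hz.
#'
#' @param profile `"exp1"`, `"exp2"` or `"custom"`.
#' @param seed master seed; every stage derives its stream from it.
#' @param n_subjects simulated participants.
#' @param race,synth,env,burst optional parameter objects overriding the
#'   profile defaults (required for `"custom"`).
#' @return List of class `run_config`.
#' @export
run_config <- function(profile = c("exp2", "exp1", "custom"), seed = 1,
                       n_subjects = 1, race = NULL, synth = NULL,
                       env = NULL, burst = NULL) {
  profile <- match.arg(profile)
  defaults <- switch(profile,
    exp2 = list(race = race_params(),
                synth = synth_params(),
                env = envelope_params(bs_band = c(48, 52)),
                burst = burst_params(peak_frac = 0.15, edge_frac = 0.10)),
    exp1 = list(race = exp1_race_params(),
                synth = exp1_synth_params(),
                env = envelope_params(bp_high = 450, bs_band = c(58, 62)),
                burst = burst_params(peak_frac = 0.10, edge_frac = 0.05)),
    custom = list(race = race, synth = synth, env = env, burst = burst))
  cfg <- list(profile = profile, seed = as.integer(seed),
              n_subjects = as.integer(n_subjects),
              race = race %||% defaults$race,
              synth = synth %||% defaults$synth,
              env = env %||% defaults$env,
              burst = burst %||% defaults$burst)
  stopifnot(inherits(cfg$race, "race_params"),
            inherits(cfg$synth, "synth_params"))
  class(cfg) <- "run_config"
  cfg
}

#' Read a run configuration from a YAML file
#'
#' Flat key-value file: `profile`, `seed`, `n_subjects` plus optional
#' sections `race`, `synth`, `env`, `burst` whose keys are passed to the
#' corresponding parameter constructors.
#'
#' @param path YAML file path.
#' @return A [run_config()] object.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  mk <- function(keys, fun) if (is.null(keys)) NULL else do.call(fun, keys)
  run_config(profile = y$profile %||% "exp2",
             seed = y$seed %||% 1,
             n_subjects = y$n_subjects %||% 1,
             race = mk(y$race, race_params),
             synth = mk(y$synth, synth_params),
             env = mk(y$env, envelope_params),
             burst = mk(y$burst, burst_params))
}

#' Per-trial EMG timing table relative to the stop signal
#'
#' Reduces a burst table to one row per stop trial: the first agonist
#' burst's onset/peak/offset and the first retained antagonist burst's
#' onset, all re-referenced to the stop signal.
#'
#' @param bursts burst table from [analyze_emg_bursts()].
#' @param trials trial table.
#' @return Data frame `trial_id`, `outcome_label`, `ag_onset_ms`,
#'   `ag_peak_ms`, `ag_offset_ms`, `ant_onset_ms` (ms after the stop
#'   signal; `NA` where no burst was detected).
#' @export
emg_timing_table <- function(bursts, trials) {
  stop_ids <- trials$trial_id[trials$trial_type == "stop"]
  out <- data.frame(trial_id = stop_ids,
                    outcome_label = trials$outcome_label[match(stop_ids, trials$trial_id)],
                    ag_onset_ms = NA_real_, ag_peak_ms = NA_real_,
                    ag_offset_ms = NA_real_, ant_onset_ms = NA_real_,
                    stringsAsFactors = FALSE)
  for (k in seq_along(stop_ids)) {
    id <- stop_ids[k]
    ssd <- trials$ssd_ms[match(id, trials$trial_id)]
    ag <- bursts[bursts$trial_id == id & bursts$channel == "agonist", ]
    if (nrow(ag) > 0) {
      first <- ag[which.min(ag$onset_ms), ]
      out$ag_onset_ms[k] <- first$onset_ms - ssd
      out$ag_peak_ms[k] <- first$peak_ms - ssd
      out$ag_offset_ms[k] <- first$offset_ms - ssd
    }
    an <- bursts[bursts$trial_id == id & bursts$channel == "antagonist", ]
    if (nrow(an) > 0)
      out$ant_onset_ms[k] <- min(an$onset_ms) - ssd
  }
  out
}

#' Analyze one participant
#'
#' Full single-subject analysis: trace-based trial classification,
#' behavioural summary (including both SSRT estimators), EMG burst timing
#' relative to the stop signal (with 1.5 x IQR outlier exclusion per
#' timing measure), and the MEP suppression time course.
#'
#' @param trials trial table.
#' @param container signal container for the same trials.
#' @param cfg a [run_config()] object.
#' @param mep_min_trials minimum included trials per MEP cell.
#' @return List with `trials` (reclassified), `behavior` (one-row data
#'   frame), `timing` (per-trial table), `timing_means` (named vector),
#'   `mep` (time-course data frame or `NULL`).
#' @export
analyze_subject <- function(trials, container, cfg, mep_min_trials = 5) {
  cls <- classify_trials(trials, container, cfg$synth)
  trials$outcome_label <- cls$outcome_label
  trials$rt_ms <- cls$rt_ms
  trials$total_rt_ms <- cls$total_rt_ms
  beh <- behavior_summary(trials, container)

  timing <- NULL
  timing_means <- c(ag_peak_early = NA_real_, ag_offset_early = NA_real_,
                    ag_peak_late = NA_real_, ag_offset_late = NA_real_,
                    ant_onset_early = NA_real_, ant_onset_late = NA_real_)
  has_go_ref <- any(trials$outcome_label == "correct_go") &&
    any(paste0("trial_", trials$trial_id[trials$outcome_label == "correct_go"])
        %in% names(container))
  if (has_go_ref && any(trials$trial_type == "stop")) {
    ids <- trials$trial_id[trials$trial_type == "stop"]
    ids <- ids[paste0("trial_", ids) %in% names(container)]
    bursts <- tryCatch(
      analyze_emg_bursts(container, trials, cfg$env, cfg$burst,
                         trial_ids = ids),
      error = function(e) NULL)
    if (!is.null(bursts)) {
      timing <- emg_timing_table(bursts, trials[trials$trial_id %in% ids, ])
      msk <- function(v) {
        v[exclude_timing_outliers(v)] <- NA
        v
      }
      for (oc in c("early_stop", "late_stop")) {
        sel <- timing$outcome_label == oc
        tag <- if (oc == "early_stop") "early" else "late"
        timing_means[paste0("ag_peak_", tag)] <-
          mean(msk(timing$ag_peak_ms[sel]), na.rm = TRUE)
        timing_means[paste0("ag_offset_", tag)] <-
          mean(msk(timing$ag_offset_ms[sel]), na.rm = TRUE)
        timing_means[paste0("ant_onset_", tag)] <-
          mean(msk(timing$ant_onset_ms[sel]), na.rm = TRUE)
      }
    }
  }

  mep <- tryCatch({
    m <- mep_measurements(container, trials, cfg$env)
    if (is.null(m) || nrow(m) == 0) NULL
    else suppression_timecourse(m, min_trials = mep_min_trials)
  }, error = function(e) NULL)

  list(trials = trials, behavior = beh, timing = timing,
       timing_means = timing_means, mep = mep)
}

#' Run the full simulate-analyze-report pipeline
#'
#' Simulates `n_subjects` participants, writes per-subject trial tables and
#' signal containers, runs the per-subject analysis, and aggregates the
#' group-level comparisons: agonist offset versus SSRT (paired contrast and
#' robust regression), antagonist onset versus SSRT, the trial type x time
#' point RM-ANOVA on MEP ratios, and precedence proportions. Identical seed
#' and configuration give an identical report.
#'
#' @param cfg a [run_config()] object.
#' @param out_dir output directory (created if needed); `NULL` to skip
#'   writing intermediate files.
#' @return The report (list); also written as `report.json` when `out_dir`
#'   is given.
#' @export
run_pipeline <- function(cfg, out_dir = NULL) {
  stopifnot(inherits(cfg, "run_config"))
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  subjects <- vector("list", cfg$n_subjects)
  for (s in seq_len(cfg$n_subjects)) {
    seed_s <- derive_seed(cfg$seed, s, 1L)
    sim <- simulate_experiment(cfg$race, cfg$synth, seed = seed_s)
    container <- synthesize_experiment(sim, cfg$synth, seed = seed_s)
    if (!is.null(out_dir)) {
      write_trials(sim$trials, file.path(out_dir,
                                         sprintf("subject%02d_trials.tsv", s)))
      write_signals(container, file.path(out_dir,
                                         sprintf("subject%02d_signals.rds", s)))
    }
    subjects[[s]] <- analyze_subject(sim$trials, container, cfg)
  }

  report <- list(profile = cfg$profile, seed = cfg$seed,
                 n_subjects = cfg$n_subjects)
  if (cfg$n_subjects > 0) {
    beh <- do.call(rbind, lapply(subjects, `[[`, "behavior"))
    beh$subject <- seq_len(cfg$n_subjects)
    tim <- do.call(rbind, lapply(subjects, `[[`, "timing_means"))
    report$behavior <- beh
    report$timing_means <- as.data.frame(tim)
    report$group <- group_stats(beh, as.data.frame(tim), subjects)
  }
  if (!is.null(out_dir))
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, na = "null",
                         dataframe = "columns")
  report
}

group_stats <- function(beh, tim, subjects) {
  out <- list()
  ok <- is.finite(beh$ssrt_rm_ms) & is.finite(tim$ag_offset_early)
  if (sum(ok) >= 3) {
    out$offset_vs_ssrt_rm <- paired_contrast(tim$ag_offset_early[ok],
                                             beh$ssrt_rm_ms[ok])
    out$offset_ssrt_rm_regression <- tryCatch({
      r <- robust_linreg(beh$ssrt_rm_ms[ok], tim$ag_offset_early[ok])
      r[c("slope", "intercept")]
    }, error = function(e) NULL)
  }
  ok2 <- is.finite(beh$ssrt_k_ms) & is.finite(tim$ag_offset_late)
  if (sum(ok2) >= 3)
    out$offset_vs_ssrt_k <- paired_contrast(tim$ag_offset_late[ok2],
                                            beh$ssrt_k_ms[ok2])
  ok3 <- is.finite(beh$ssrt_k_ms) & is.finite(tim$ant_onset_late)
  if (sum(ok3) >= 3)
    out$ant_onset_vs_ssrt_k <- paired_contrast(tim$ant_onset_late[ok3],
                                               beh$ssrt_k_ms[ok3])

  # precedence: per-trial agonist offsets vs the subject's SSRT estimate
  prec_rm <- prec_k <- rep(NA_real_, nrow(beh))
  for (s in seq_len(nrow(beh))) {
    tt <- subjects[[s]]$timing
    if (is.null(tt)) next
    early <- tt$outcome_label == "early_stop"
    late <- tt$outcome_label == "late_stop"
    if (is.finite(beh$ssrt_rm_ms[s]))
      prec_rm[s] <- precedence_proportion(tt$ag_offset_ms[early],
                                          beh$ssrt_rm_ms[s])
    if (is.finite(beh$ssrt_k_ms[s]))
      prec_k[s] <- precedence_proportion(tt$ag_offset_ms[late],
                                         beh$ssrt_k_ms[s])
  }
  out$precedence_offset_before_ssrt_rm <- mean(prec_rm, na.rm = TRUE)
  out$precedence_offset_before_ssrt_k <- mean(prec_k, na.rm = TRUE)

  # MEP RM-ANOVA over subjects with complete cells
  cells <- lapply(seq_along(subjects), function(s) {
    m <- subjects[[s]]$mep
    if (is.null(m) || any(is.na(m$mean_ratio))) return(NULL)
    cbind(subject = s, m[, c("trial_type", "tms_timepoint_ms", "mean_ratio")])
  })
  cells <- do.call(rbind, cells[!vapply(cells, is.null, logical(1))])
  if (!is.null(cells) && length(unique(cells$subject)) >= 3) {
    names(cells)[names(cells) == "mean_ratio"] <- "value"
    out$mep_anova <- tryCatch(rm_anova(cells), error = function(e) NULL)
  }
  out
}
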