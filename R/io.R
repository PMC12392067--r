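# Persistent structures: trial-events tables (TSV) and per-trial multichannel
# signal containers (hierarchical RDS: trial -> channel -> fs/t0_ms/samples).

TRIAL_COLUMNS <- c("trial_id", "block", "trial_type", "ssd_ms", "tms_time_ms",
                   "go_onset_ms", "response", "rt_ms", "total_rt_ms",
                   "outcome_label")
OUTCOME_LEVELS <- c("correct_go", "go_error_wrongdir", "go_omission",
                    "early_stop", "late_stop", "trigger_failure")
EMG_CHANNELS <- c("agonist", "antagonist", "task_irrelevant")

validate_trials <- function(trials) {
  if (!is.data.frame(trials)) stop("trials must be a data frame")
  missing <- setdiff(TRIAL_COLUMNS, names(trials))
  extra <- setdiff(names(trials), TRIAL_COLUMNS)
  if (length(missing) > 0)
    stop("trial table missing columns: ", paste(missing, collapse = ", "))
  if (length(extra) > 0)
    stop("trial table has unknown columns: ", paste(extra, collapse = ", "))
  if (nrow(trials) == 0) return(invisible(trials))
  if (is.unsorted(trials$trial_id, strictly = TRUE))
    stop("trial_id must be strictly increasing")
  if (!all(trials$trial_type %in% c("go", "stop")))
    stop("trial_type must be 'go' or 'stop'")
  if (!all(trials$outcome_label %in% OUTCOME_LEVELS))
    stop("unknown outcome_label values")
  is_stop <- trials$trial_type == "stop"
  if (any(is.na(trials$ssd_ms[is_stop])) || any(trials$ssd_ms[is_stop] < 0))
    stop("stop trials must have ssd_ms >= 0")
  both <- !is.na(trials$rt_ms) & !is.na(trials$total_rt_ms)
  if (any(trials$rt_ms[both] > trials$total_rt_ms[both]))
    stop("rt_ms must not exceed total_rt_ms")
  invisible(trials)
}

#' Read and write trial-events tables
#'
#' Trial tables are UTF-8 tab-separated text with a one-line header and
#' exactly the trial-record columns (`trial_id`, `block`, `trial_type`,
#' `ssd_ms`, `tms_time_ms`, `go_onset_ms`, `response`, `rt_ms`,
#' `total_rt_ms`, `outcome_label`); decimal point is `.`, missing values are
#' `NA`. All per-trial times are ms with 0 at the go signal; on go trials
#' `ssd_ms` holds the yoked SSD. Schema violations (missing or extra
#' columns, non-monotone `trial_id`, stop trials without an SSD) are errors:
#' no partial loads.
#'
#' @param trials data frame with the schema above.
#' @param path file path.
#' @return `read_trials` returns the validated data frame; `write_trials`
#'   returns `path` invisibly.
#' @export
write_trials <- function(trials, path) {
  validate_trials(trials)
  utils::write.table(trials[, TRIAL_COLUMNS, drop = FALSE], path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  trials <- utils::read.delim(path, sep = "\t", header = TRUE,
                              stringsAsFactors = FALSE,
                              colClasses = c(trial_id = "integer",
                                             block = "integer",
                                             trial_type = "character",
                                             ssd_ms = "numeric",
                                             tms_time_ms = "numeric",
                                             go_onset_ms = "numeric",
                                             response = "character",
                                             rt_ms = "numeric",
                                             total_rt_ms = "numeric",
                                             outcome_label = "character"),
                              fileEncoding = "UTF-8")
  validate_trials(trials)
  trials
}

validate_signals <- function(container) {
  if (!is.list(container)) stop("signal container must be a list")
  for (nm in names(container)) {
    trial <- container[[nm]]
    if (!is.list(trial) || is.null(names(trial)))
      stop("trial ", nm, ": expected a named list of channels")
    fss <- numeric(0)
    for (ch in names(trial)) {
      sig <- trial[[ch]]
      if (!all(c("channel", "fs", "t0_ms", "samples") %in% names(sig)))
        stop("trial ", nm, " channel ", ch,
             ": need channel, fs, t0_ms, samples")
      if (!is.numeric(sig$samples))
        stop("trial ", nm, " channel ", ch, ": samples must be numeric")
      if (ch %in% EMG_CHANNELS) fss <- c(fss, sig$fs)
    }
    if (length(unique(fss)) > 1)
      stop("trial ", nm, ": sampling-rate mismatch across EMG channels")
  }
  invisible(container)
}

#' Read and write per-trial signal containers
#'
#' Signals are stored in a hierarchical R-native container (RDS):
#' one entry per trial (`trial_<id>`), one sampled signal per channel, each
#' holding its sampling rate `fs` (Hz), time origin `t0_ms` (ms relative to
#' the go signal) and `samples` (mV, or px for displacement). Round trips
#' are numerically exact. A sampling-rate mismatch across the EMG channels
#' of one trial is an error; the displacement channel may differ.
#'
#' @param container named list of trials, each a named list of sampled
#'   signals.
#' @param path file path.
#' @return `read_signals` returns the validated container; `write_signals`
#'   returns `path` invisibly.
#' @export
write_signals <- function(container, path) {
  validate_signals(container)
  attr(container, "stopdyn_signals") <- 1L
  saveRDS(container, path)
  invisible(path)
}

#' @rdname write_signals
#' @export
read_signals <- function(path) {
  container <- readRDS(path)
  if (is.null(attr(container, "stopdyn_signals")))
    stop("not a stopdyn signal container: ", path)
  validate_signals(container)
  container
}
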