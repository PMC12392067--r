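# Inferential layer: paired contrasts, robust regression, RM-ANOVA,
# precedence proportions.

#' Paired contrast with effect size
#'
#' Paired-sample t test between two per-subject measures, with Cohen's d
#' computed on the paired differences (mean difference divided by the
#' standard deviation of the differences).
#'
#' @param a,b numeric vectors of per-subject values, same length and order.
#' @return List with `mean_diff`, `t_stat`, `df`, `p_value`, `cohens_d`,
#'   `n_subjects`.
#' @export
paired_contrast <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2)
  ok <- !is.na(a) & !is.na(b)
  d <- a[ok] - b[ok]
  n <- length(d)
  sd_d <- stats::sd(d)
  if (sd_d == 0) {
    # identical pairs: no variability to test against
    t_stat <- if (mean(d) == 0) 0 else sign(mean(d)) * Inf
    return(list(mean_diff = mean(d), t_stat = t_stat, df = n - 1,
                p_value = if (mean(d) == 0) 1 else 0,
                cohens_d = if (mean(d) == 0) 0 else sign(mean(d)) * Inf,
                n_subjects = n))
  }
  tt <- stats::t.test(a[ok], b[ok], paired = TRUE)
  list(mean_diff = mean(d),
       t_stat = unname(tt$statistic),
       df = unname(tt$parameter),
       p_value = tt$p.value,
       cohens_d = mean(d) / sd_d,
       n_subjects = n)
}

#' Robust linear regression (iteratively reweighted bisquare)
#'
#' M-estimation with Tukey's bisquare weights and tuning constant 4.685
#' (95% Gaussian efficiency) — the estimator behind MATLAB's `robustfit`.
#' Fitted by iteratively reweighted least squares via [MASS::rlm()].
#'
#' @param x,y numeric vectors.
#' @return List with `slope`, `intercept`, `weights` (final robust
#'   weights), and the underlying `fit`.
#' @export
robust_linreg <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::sd(x) == 0) stop("x is constant: design is rank deficient")
  fit <- MASS::rlm(y ~ x, psi = MASS::psi.bisquare, c = 4.685,
                   maxit = 1000, acc = 1e-8)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       weights = fit$w,
       fit = fit)
}

#' Two-way repeated-measures ANOVA
#'
#' Within-subject ANOVA with two crossed factors (trial type and TMS time
#' point) using univariate F tests with subject-by-factor error strata, as
#' produced by `aov` with an `Error(subject/(type * time))` term. The
#' design must be complete and balanced: every subject contributes one
#' value per cell.
#'
#' @param data data frame with columns `subject`, `trial_type`,
#'   `tms_timepoint_ms`, `value` (one row per subject x cell).
#' @return Data frame with rows `trial_type`, `tms_timepoint_ms` and their
#'   interaction: `df1`, `df2`, `F`, `p_value`.
#' @export
rm_anova <- function(data) {
  need <- c("subject", "trial_type", "tms_timepoint_ms", "value")
  stopifnot(all(need %in% names(data)))
  if (any(is.na(data$value))) stop("missing cell values: design must be complete")
  d <- data.frame(subject = factor(data$subject),
                  type = factor(data$trial_type),
                  time = factor(data$tms_timepoint_ms),
                  value = data$value)
  counts <- table(d$subject, d$type, d$time)
  if (any(counts != 1))
    stop("unbalanced design: every subject needs exactly one value per cell")
  fit <- stats::aov(value ~ type * time + Error(subject / (type * time)),
                    data = d)
  s <- summary(fit)
  pick <- function(stratum, term) {
    tab <- s[[paste0("Error: subject:", stratum)]][[1]]
    i <- grep(term, rownames(tab))
    c(df1 = tab[i, "Df"], df2 = tab[nrow(tab), "Df"],
      F = tab[i, "F value"], p = tab[i, "Pr(>F)"])
  }
  main_type <- pick("type", "^type")
  main_time <- pick("time", "^time")
  inter <- pick("type:time", "type:time")
  data.frame(effect = c("trial_type", "tms_timepoint_ms", "interaction"),
             df1 = c(main_type["df1"], main_time["df1"], inter["df1"]),
             df2 = c(main_type["df2"], main_time["df2"], inter["df2"]),
             F = c(main_type["F"], main_time["F"], inter["F"]),
             p_value = c(main_type["p"], main_time["p"], inter["p"]),
             row.names = NULL)
}

#' Per-trial precedence proportion
#'
#' Fraction of trials on which an event (e.g. the EMG offset, optionally
#' shifted back by the corticomuscular conduction time) precedes a reference
#' latency such as the SSRT.
#'
#' @param event_times_ms per-trial event times (ms; `NA` ignored).
#' @param reference_ms reference latency (ms, same time base).
#' @param shift_ms subtracted from each event time before comparison
#'   (default 0; set to the conduction time to compare cortical command
#'   offsets).
#' @return Proportion in `[0, 1]`.
#' @export
precedence_proportion <- function(event_times_ms, reference_ms,
                                  shift_ms = 0) {
  ev <- event_times_ms[!is.na(event_times_ms)]
  if (length(ev) == 0) return(NA_real_)
  mean((ev - shift_ms) < reference_ms)
}
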