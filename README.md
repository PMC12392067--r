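# stopdyn

Trial-level analysis of stop-signal task recordings, for motor
neurophysiologists studying how humans cancel actions: electromyographic
(EMG) burst timing in agonist and antagonist muscles, two estimators of the
stop-signal reaction time (SSRT), and the time course of corticospinal
suppression probed with transcranial magnetic stimulation (TMS). A built-in
synthetic-data generator — an independent horse-race model with an adaptive
stop-signal-delay staircase plus a forward model for EMG, cursor kinematics
and motor-evoked potentials (MEPs) — gives every estimator a known ground
truth, so the whole pipeline is validated by parameter recovery with no
data download.

## The models in brief

**Race model.** Each stop trial is a race between a go process with
ex-Gaussian finishing time *T*<sub>go</sub> and a stop process with
zero-truncated-normal finishing time *T*<sub>stop</sub> launched at the
stop-signal delay (SSD): stopping succeeds iff SSD + *T*<sub>stop</sub> <
*T*<sub>go</sub>. The SSD follows a 1-up/1-down staircase that converges on
50% stopping. Trigger failures (stop process never launched) occur with a
configurable probability.

**SSRT estimators.**
*Integration method* (race-model based): omitted go RTs are replaced with
the maximum observed RT, go RTs are sorted, and
SSRT<sub>RM</sub> = RT<sub>(⌈p·n⌉)</sub> − mean SSD, where *p* is the
probability of responding given a stop signal.
*Kinematic method* (model-free): the time of peak cursor velocity on late
stop trials, relative to the stop signal, marks when the go command was
curtailed (SSRT<sub>K</sub>); per-trial values are averaged after 1.5×IQR
outlier exclusion.

**EMG chain.** TMS artifact interpolation (−1 to +1.5 ms), second-order
Butterworth band-pass and mains band-stop (zero-phase), full-wave
rectification, centred 20 ms RMS. Bursts are peaks above 10–15% of the
mean correct-go peak; onsets/offsets are found by backtracking to a
≥ 20 ms run below 5–10% of the burst's own peak. Antagonist bursts
starting within 50 ms of the stop signal are excluded as postural rises.

**MEPs.** Peak-to-peak amplitude 18–48 ms after the pulse, gated on
< 0.05 mV background in the preceding 100 ms, normalized to the go-signal
baseline, and averaged per trial type × TMS time point; the inferential
layer provides paired contrasts with Cohen's *d*, robust bisquare
regression, a trial type × time repeated-measures ANOVA, and per-trial
precedence proportions.

See `vignettes/stopdyn-methods.Rmd` for the full account, including the
forward model and its self-calibration.

## Worked example

Simulate one participant of the whole-arm reaching variant (4 blocks of 96
trials here; the full experiment uses 12), render the signals, and run the
complete single-subject analysis:

```r
library(stopdyn)

race  <- race_params(n_blocks = 4, trials_per_block = 96)
synth <- synth_params()                      # 4 kHz reaching profile
sim   <- simulate_experiment(race, synth, seed = 1)
cont  <- synthesize_experiment(sim, synth, seed = 1)
res   <- analyze_subject(sim$trials, cont, run_config("exp2"))

round(res$behavior[, 1:6], 1)
#>   n_trials go_rt_ms go_total_rt_ms late_stop_rt_ms mean_ssd_ms p_stop
#> 1      384    489.5          841.4           407.5       197.2    0.5

round(res$behavior[, 7:10], 1)
#>   ssrt_rm_ms ssrt_k_ms trigger_failure_pct go_error_pct
#> 1      270.3     239.6                 4.2          8.3

round(res$timing_means, 1)
#>   ag_peak_early ag_offset_early    ag_peak_late  ag_offset_late
#>           240.9           270.3           153.6           256.2
#> ant_onset_early  ant_onset_late
#>           269.8           274.8
```

Reading the output: the staircase held stopping probability at 0.50; the
integration SSRT (270 ms) recovers the generator's mean stop latency
(`true_mean_stop_latency(race)` = 264 ms) at this trial count; failed-stop
(late stop) RTs are faster than go RTs (408 vs 490 ms), as the race model
predicts; and the agonist offsets and antagonist onsets (ms after the stop
signal) precede or bracket the SSRT estimates. The MEP table in `res$mep`
shows early-stop amplitude ratios suppressed toward 0.7 at the 150–300 ms
time points (injected depth 0.3) with go trials flat at 1.

`run_pipeline(run_config("exp2", seed = 1, n_subjects = 20), out_dir)`
runs the same analysis for a cohort, writes per-subject trial tables
(TSV) and signal containers (RDS), and aggregates the group statistics
into `report.json`. A thin command-line wrapper with `simulate`, `emg`,
`behavior`, `mep` and `all` subcommands lives at `inst/cli/stopdyn.R`.

## File formats

* **Trial tables** — UTF-8 TSV, one header line, columns exactly:
  `trial_id, block, trial_type, ssd_ms, tms_time_ms, go_onset_ms,
  response, rt_ms, total_rt_ms, outcome_label`. Times in ms with 0 at the
  go signal; on go trials `ssd_ms` holds the yoked SSD.
* **Signal containers** — R-native RDS with a hierarchical layout:
  `trial_<id>` → channel (`agonist`, `antagonist`, `task_irrelevant`,
  `displacement`) → `{fs, t0_ms, samples}`. Round trips are exact.

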