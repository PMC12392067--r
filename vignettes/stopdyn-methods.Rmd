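---
title: "Models and methods behind stopdyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind stopdyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stopdyn)
```

`stopdyn` analyses stop-signal task recordings at the single-trial level —
EMG burst timing, two estimators of the stop-signal reaction time (SSRT),
and TMS-probed corticospinal suppression time courses — and ships a
synthetic-data generator so that every estimator in the pipeline can be
validated by parameter recovery against known ground truth. This vignette
explains the models, the tunable parameters, and the design decisions; it
states no empirical result that the package's tests and scripts do not
themselves compute.

## The task and the race model

In a stop-signal task, most trials are *go* trials (respond to a cue); on a
minority, a stop signal appears after a variable stop-signal delay (SSD)
and the participant tries to withhold or interrupt the response. The
canonical analysis treats each stop trial as an independent horse race: a
go process with finishing time $T_{go}$ races a stop process with finishing
time $T_{stop}$ started at the SSD, and stopping succeeds iff
$\mathrm{SSD} + T_{stop} < T_{go}$.

The generator draws $T_{go}$ from an ex-Gaussian
($\mu, \sigma, \tau$; mean $\mu + \tau$) — the conventional family for
response-time distributions — and $T_{stop}$ from a normal truncated at
zero ($\mu_s, \sigma_s$); the literature rarely commits to a stop-latency
family, so a two-parameter symmetric choice keeps the ground-truth mean
interpretable (`true_mean_stop_latency()`). With probability
`p_trigger_failure` the stop process never starts and the trial runs as a
go trial. The SSD follows a 1-up/1-down staircase (`update_ssd()`):
+1 step after a successful stop, −1 step after a failed one, floored at
0 ms with no ceiling (the staircase self-limits). This tracks the 50%
stopping point, which the convergence tests verify.

Two parameter profiles bind the two task variants: a ballistic key-press
variant (1 kHz EMG, 50 ms steps, burst thresholds 10%/5%, 58–62 Hz
band-stop, 23.3 ms corticomuscular conduction) and a whole-arm reaching
variant (4 kHz, ~33.3 ms steps, 15%/10%, 48–52 Hz, 9.6 ms conduction).
Go-trial TMS pulses are yoked to the preceding stop trial's SSD (the
initial SSD before any stop trial has occurred), and one in six stop trials
carries no pulse.

## The forward signal model

The generator renders each trial's latent timings into three EMG channels
(agonist, antagonist, task-irrelevant), a signed cursor-displacement trace
(positive toward the cued target), and TMS artifacts/MEPs.

**Envelopes.** The agonist burst envelope rises as a raised cosine over
`rise_ms` (50 ms) and decays exponentially with `decay_ms` (120 ms) on
uninterrupted trials. On triggered stop trials the cortical command ends at
`cmd_offset_ms`; one conduction delay later the envelope is forced into a
raised-cosine decline lasting `fall_ms` (30 ms — the peak-to-offset
interval observed on successful stops), reaching baseline at the latent
offset. Reactive antagonist bursts (rise 40 ms) begin one `ant_gap_ms`
after agonist offset; their presence probability and amplitude differ by
trial type, and a small fraction of stop trials instead carry a slow
postural antagonist rise starting right after the stop signal — the events
the 50 ms early-onset exclusion rule is designed to remove. A secondary
tonic agonist bout, with amplitude proportional to the final displacement
(`tonic_gain`), models postural stabilization after the reach; it
contributes to the EMG but not to the kinematic drive.

**EMG synthesis.** The raw trace is the envelope multiplied by white
Gaussian noise (an interference-pattern carrier), plus additive baseline
noise (`noise_sd`, 0.01 mV) and mains hum. With `noise_sd = 0` the
deterministic envelope is returned, which the noiseless validation tests
rely on. TMS pulses inject a ~1 ms artifact on every EMG channel.

**Kinematics.** The cursor obeys first-order damped dynamics driven by the
net phasic drive (agonist − antagonist braking),
$\dot v = (g\,d(t) - v)/\tau$, with `kin_tau_ms = 400` — long relative to
the burst, so the model operates in an inertial regime where velocity
peaks near the zero crossing of the net drive, i.e. at the
agonist-offset/antagonist-onset transition. Below a static drive threshold
the damping switches to a short `kin_freeze_tau_ms` (15 ms), so residual
momentum settles rather than drifting indefinitely (static friction); the
cursor is clamped inside the home pad until the *agonist* drive exceeds
the threshold — a braking burst alone never unclamps it. On braked trials
the cursor freezes at the first velocity reversal.

**Self-calibration.** `calibrate_kinematics()` solves the noiseless
go-trial once per parameter set and fixes: the gain that lands a full
reach on the target centre; the lead of EMG onset over home-pad exit (so a
latent go finishing time *is* the trial's RT); the movement duration; and
the critical truncation lag — the latest command cut-off for which the
cursor still never leaves the home pad. The EMG-offset lead over the
behavioural stop-completion time is derived from these constants, which
makes the trace-level outcome (exits the home pad or not) coincide with
the latent race inequality. A notable consequence: the per-trial offset
lead is small (a few ms), yet the mean agonist offset on successful stops
still precedes the SSRT estimate by tens of milliseconds, because stop
trials that win the race have conditionally *early* stop latencies — the
selection effect that the estimators then quantify.

**MEPs.** MEP peak-to-peak amplitudes are log-normal around `mep_base_mv`
(1 mV; dispersion `mep_sigma_log = 0.35`, a typical resting MEP
coefficient of variation), scaled by $(1 - d)$ with suppression depth
$d = 0.3$ when the pulse falls inside the trial-type's suppression window:
150–300 ms after the stop signal on early stops, 150 ms only on late stops
(suppression is withdrawn as braking takes over), none on go trials. The
injected waveform is a damped sinusoid starting `mep_latency_ms` after the
pulse, scaled so its window peak-to-peak equals the drawn amplitude
exactly.

## The analysis pipeline

**EMG preprocessing.** TMS artifacts are linearly interpolated from 1 ms
before to 1.5 ms after each pulse; signals are band-pass filtered
(second-order Butterworth, 10–2000 Hz, capped below Nyquist — the 1 kHz
profile uses 10–450 Hz since its hardware band-limited the signal before
digitization), band-stop filtered around the mains frequency, full-wave
rectified, and smoothed with a centred 20 ms RMS window that shrinks at
the signal edges (no invented data). Filtering is zero-phase
(forward–backward) by default to preserve burst timing — consistent with a
24 dB/octave roll-off from a doubled effective order — with a causal
option in `envelope_params()`.

**Burst detection.** Candidate peaks are local envelope maxima at or above
`peak_frac` of the mean correct-go peak (plateaus resolve to their
earliest sample). From each peak, the onset is the first sample after the
nearest run of ≥ `min_dwell_ms` consecutive samples below `edge_frac` of
the burst's own peak (a config switch references the go peak instead);
offsets mirror forward. Sub-dwell dips do not split a burst. Overlapping
candidates resolve strongest-first to the dominant candidate's interval:
with per-peak edge thresholds, weak shoulder candidates would otherwise
carry thresholds below the noise floor and smear onsets outward. The
validation suite holds this detector to exact agreement with an
independent exhaustive-scan oracle on 1,000 random envelopes.

**Behaviour.** `classify_trials()` applies the operational rules to the
displacement traces: any excursion beyond the home-pad half-width is a
response; stop trials split into early stops (never exit), late stops
(exit, never reach the target) and trigger failures (reach the target); go
trials are checked for wrong-direction errors (wrong side of the midpoint
for ≥ 6 display frames, with a small dead band around zero so sensor
jitter cannot trip the rule) and omissions (no target entry within 1.5 s).
`integration_ssrt()` implements the integration method with omission
replacement at the maximum observed RT and the 1-based `ceiling(p × n)`
rank; degenerate response probabilities (0 or 1) are flagged undefined
rather than extrapolated. Wrong-direction go trials count as responses and
keep their RTs in the integration distribution by default (they are
excluded from timing and MEP analyses); a switch drops them.
`kinematic_ssrt()` takes per-trial peak times of the centred-difference
velocity (smoothed with a 20 ms moving average, mirroring the RMS window),
excludes flat traces and 1.5×IQR timing outliers, and averages; the
participant value is the mean of per-trial values.

**MEPs.** Peak-to-peak amplitude is read from the raw band-passed signal
18–48 ms after the pulse; a measurement is included only when mean
rectified background in the preceding 100 ms is strictly below 0.05 mV
(the summary statistic is configurable; the threshold comparison is
strict, so exactly 0.05 mV excludes). Ratios are taken to the subject's
mean included go-signal amplitude and averaged per trial type × time
point; in the group pipeline a subject contributes to a cell only with ≥ 5
included trials, which stabilizes cell means. Corticomuscular conduction
time is the minimum MEP onset latency across stimuli.

**Inference.** Paired contrasts use the paired t statistic with Cohen's
*d* on the difference scores (the paired-differences denominator;
identical inputs return t = 0 rather than an error); robust regression is
iteratively reweighted bisquare M-estimation with tuning constant 4.685
via `MASS::rlm`; the MEP analysis is a two-way within-subject ANOVA
(trial type × time point) with subject-by-factor error strata, requiring a
complete balanced design; precedence proportions count trials whose event
time (optionally shifted back by the conduction time) precedes a reference
latency. No multiple-testing correction is applied, matching the uncorrected
post hoc convention; a flag can change that.

## Timing-outlier and quantile conventions

The 1.5×IQR rule uses linearly interpolated quartiles (`quantile`
type 7), the most common convention, stated here for reproducibility.
Outliers are flagged per measure within participant; fewer than four
values yield no flags (with a warning) rather than an error, since small
cells occur in short recordings.

## What the validation shows — and what it cannot

The test suite validates the pipeline on generator output at specific
problem sizes, chosen to exercise the estimators at realistic trial
counts while keeping a full run in minutes: staircase convergence on
12 × 96-trial experiments; detector-oracle equivalence on 1,000 random
envelopes; timing recovery on 20 simulated participants × 288 stop trials
at 4 kHz (with 48 go trials per participant for the reference peak — the
only go trials the timing measurement consumes); integration-SSRT recovery
at ~10,000 trials; suppression-depth recovery at 48 trials per time point
across 20 participants; 100-cohort checks of the race-model ordering
(signal-respond RT < go RT); a demonstration that stop-aligned grand
averages smear the apparent offset beyond the mean of per-trial offsets
once offset jitter reaches ~30 ms (why trial-level timing, not average
waveforms, is analysed); and 500-cohort type-I calibration of the ANOVA
under the null generator.

Passing these tests shows the estimators are faithful to *this* generative
model. The generator emulates ex-Gaussian/truncated-normal finishing
times, context independence by construction, staircase dynamics, trigger
failures, graded partial bursts, reactive braking, postural bouts,
multiplicative EMG noise, mains hum, TMS artifacts and log-normal MEP
variability. It does not emulate: violations of context independence,
proactive slowing across blocks, motor-unit-level EMG structure,
electrode artifacts or movement cross-talk, 2-D curved trajectories (the
displacement is a signed 1-D resultant), or trial-history effects beyond
the staircase. Real-data performance on those axes is therefore not
certified by the suite.

## Known limitations

* The first-order inertial cursor places the velocity peak at the
  net-drive transition; real limbs add electromechanical delays, so the
  kinematic stopping marker in the synthetic world sits earlier relative
  to the race-completion time than in real reaching data. Each estimator
  is validated against its own generator truth.
* The integration SSRT estimator inherits a small negative bias when the
  staircase step is large (≈5–12 ms at 50 ms steps in our measurements);
  recovery claims are therefore stated for the fine-stepped reaching
  profile.
* Envelope-threshold onset detection necessarily lags a finite-rise-time
  envelope; with the default shapes the residual systematic error is a few
  milliseconds, inside the stated recovery tolerances but not zero.
* The go-trial MEP facilitation sometimes seen ~100 ms after a (yoked)
  stop signal is not modelled; go-trial MEP ratios are flat at 1 by
  construction.
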