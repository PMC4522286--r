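---
title: "Quantifying components of manual dexterity from four-channel fingertip force recordings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying components of manual dexterity from four-channel fingertip force recordings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ffm)
```

## The measurement problem

Manual dexterity is not a single quantity. Clinically useful assessment after
stroke has to separate at least four components: the ability to *control
force* with a finger, the ability to *move fingers independently* of each
other, the ability to *time* repetitive movements, and the ability to
*sequence* finger movements. A four-piston finger force manipulandum — one
strain-gauge force sensor under the index, middle, ring and little finger —
measures all four with one apparatus: the subject presses spring-loaded
pistons while following visual or auditory cues, and everything downstream is
computed from the four force time series \(F_d(t)\) in newtons.

This package implements that downstream analysis as a complete, testable
pipeline: protocol construction for the four tasks, recording I/O and
validation, per-task performance metrics, and individual profiling against
control norms. Because no public recordings of this kind of device exist, the
package also contains a seedable generative model of control-like and
paretic-like traces with exported ground-truth events, so that every analysis
stage can be verified against what was actually generated.

## The four tasks and their schedules

* **Force tracking** (`build_tracking_protocol()`): each trial is a 1.5 s
  linear ramp to the target force, a 4 s hold, an instantaneous release of
  the displayed target back to rest and a 2 s resting phase. 24 trials in
  four blocks of six, two blocks at 1 N and two at 2 N. The low force levels
  matter: dexterous manipulation operates at forces of a few newtons at most.
* **Sequential tapping** (`build_sequence_protocol()`): a five-tap sequence
  over the four digits (the three standard sequences are A = 2-5-3-4-2,
  B = 4-3-5-2-4, C = 3-2-4-5-3 with 2 = index … 5 = little), cued visually at
  1 Hz for ten repeats (learning phase) and then recalled five times without
  cues. Each repeat occupies a 5 s trial window; recall trials use the same
  window even though recall is self-paced.
* **Single finger tapping** (`build_single_tap_protocol()`): repetitive
  tapping of one finger at 1, 2 and 3 Hz, 15 metronome-cued taps followed by
  an uncued continuation phase of equal duration, ordered frequency-major
  (index → little within each rate).
* **Multi-finger tapping** (`build_multi_tap_protocol()`): visually cued taps
  of the 4 one-finger, 6 two-finger and 1 four-finger configurations,
  repeated 8, 5 and 2 times respectively — 64 cues in pseudo-random order.
  The order is a seeded permutation constrained so the counts of one-to-two
  and two-to-one finger transitions differ by at most one; since no published
  ordering algorithm exists, rejection sampling (capped at 10 000 draws, then
  best-effort with a warning) implements the constraint.

Two schedule parameters are genuinely under-determined and are therefore
explicit, documented defaults rather than constants: the tracking task's
stated per-digit duration cannot be reconciled exactly with 24 × 7.5 s
trials, so `total_duration` is always computed from the schedule; and the
multi-finger inter-trial interval is not stated, so the default 4.375 s is
chosen to make 64 trials span 280 s, and is configurable.

## Recordings

A recording is a `[n × 4]` matrix of forces at a known rate with metadata
(`force_recording()`), serialized as a plain CSV trace
(`t,index,middle,ring,little`) plus a JSON sidecar — the most portable choice
for a device with no standard file format. The sensors have a nominal 0–9 N
range and < 0.01 N precision; `validate_recording()` reports out-of-range
samples as warnings rather than errors because impaired subjects can exceed
the nominal range transiently. All analyses run at 100 Hz; `resample_to()`
performs anti-aliased decimation (zero-phase 4th-order Butterworth at 90 % of
the target Nyquist, applied around the signal mean so constants pass through
exactly, then linear interpolation onto the target grid). The anti-alias
filter is the package's own choice; no particular filter is canonical for
this application, and any filter flat below ~10 Hz gives indistinguishable
metrics, since tap and tracking energy live well below that.

## Tracking metrics

All tracking measures are computed trial by trial and averaged per target
force, with undefined values propagating as `NA`, never as zeros:

* **RMSE** between the measured force and the commanded trapezoid target
  (not the rendered cursor), separately for ramp and hold.
* **Force onset / release onset** as threshold crossings of the derivative
  of a 50 ms moving-average-smoothed trace. No published threshold exists;
  the default is ±0.4 N/s. A steeper default (e.g. 1 N/s) would silently make
  onsets undefined for clean 1 N trials, whose commanded ramp slope is only
  2/3 N/s. On strongly noisy traces the derivative of white noise dominates
  and onset times saturate near the cue — onset timing is retained for
  completeness but is the least robust measure in the set.
* **Release duration**: the time for force to fall from 75 % to 25 % of the
  target after the hold, with linear interpolation between samples. The
  estimator recovers τ·ln 3 for exponential releases to within one sample
  period over τ ∈ [0.05, 1] s, and is `NA` when force never falls below the
  25 % level (incomplete release, a hallmark of impaired relaxation). The
  search window opens one sample before the hold end so that an
  instantaneous release is not missed at the boundary.
* **Hold statistics**: mean force and coefficient of variation (sample
  SD/mean) over the central 3 s of the hold (500 ms trimmed at each end).
* **Baseline force**: mean force from 1.5 s to 0.5 s before each ramp onset;
  undefined for the first trial, which has no preceding rest.

## Tap detection and tapping metrics

A tap is a discrete event exceeding 0.5 N: an event starts at the upward
threshold crossing, peaks at the local maximum, ends at the downward
crossing, and events separated by less than a 100 ms refractory interval are
merged (the refractory default is the package's choice; physiological taps
cannot repeat that fast at these forces).

* **Sequential task**: the ordered user tap string is aligned to the
  five-digit target by longest common subsequence. LCS is the canonical
  choice for counting correct, missing and extra taps under insertions and
  deletions; the longest *contiguous* match (longest common substring) is
  reported as the consecutive-correct-run measure, and a trial is correct
  only when the full string matches exactly. Per-phase success rates and the
  first-half/second-half mean correct taps of the learning phase quantify
  learning.
* **Single-finger task**: per condition (finger × rate × cued/uncued), the
  lead-finger tap count, achieved rate and inter-tap intervals; each
  non-lead event within ±100 ms of a lead tap peak is an *overflow tap*
  (motor overflow), otherwise an *unwanted finger tap*. The coincidence
  half-window is configurable — "simultaneous" has no stated tolerance — and
  ±100 ms spans the sensorimotor synchronization error range. The
  **rate slope** is the least-squares slope of achieved rate (cued and
  uncued pooled) against target frequency across 1–3 Hz: 1 means veridical
  pacing, below 1 slowed execution.
* **Multi-finger task**: the response to each cue is the set of fingers with
  a detected tap in the half-open window from the cue to the next cue
  (capped at the inter-trial interval). A trial is correct iff the response
  set equals the target set; omitted target fingers and extra-finger taps
  are tallied into an omission rate, unwanted-extra-finger-tap (UEFT) counts
  per condition class, and a 10 × 4 error matrix giving, per target
  combination, the percentage of trials in which each non-target finger
  tapped erroneously. Four-finger trials are parsed but excluded from all
  rates.

## The generative model

The simulator is deliberately phenomenological — it reproduces the features
the analyzer measures, not muscle physiology:

* **Tracking**: the lead finger follows the target trapezoid delayed by a
  visuo-motor lag, rides on a constant residual baseline offset, releases
  exponentially with time constant τ toward baseline (so the measured
  release duration has the closed form τ·ln 3), and carries white Gaussian
  force noise. Non-lead channels are the enslaving-scaled lead trace plus
  noise.
* **Tapping**: every non-omitted cued finger produces a raised-cosine pulse
  (default peak 2 N, the instructed tap force) near cue time plus a reaction
  latency and Gaussian jitter; one jitter draw is shared by a cue's pulses so
  each finger's contribution stays a single closed-form pulse. A 4 × 4
  enslaving matrix transmits scaled copies of each pulse to the other
  fingers; an enslaved pulse *is* an overflow tap exactly when its trace
  peak crosses the 0.5 N detection threshold, which ties the generative
  model to the analyzer's event definition. Intended taps arriving faster
  than the subject's rate ceiling are dropped (so a 2.4 Hz ceiling produces
  the characteristic failure to follow the 3 Hz condition), uncued phases
  and recall trials are self-paced, omissions and spontaneous extra taps are
  Bernoulli events, and ground truth lists every supra-threshold event. The
  recorded ground-truth peak time and amplitude describe the *sampled*
  trace (the value at the grid point nearest the continuous peak), keeping
  truth and trace consistent to machine precision.

Two presets define the study conditions. `control_like`: 0.04 N tracking
noise, 120 ms lag, τ = 50 ms, 0.02 N baseline, 5 Hz rate ceiling,
near-diagonal enslaving (neighbors 0.05), 1 % omissions and extras.
`paretic_like`: 0.12 N noise, 250 ms lag, τ = 450 ms (release duration
≈ 0.49 s), 0.28 N baseline, 2.4 Hz ceiling, enslaving decaying with
anatomical distance (0.45 / 0.12 / 0.03 for distance 1 / 2 / 3), 15 %
omissions, 20 % extra taps. The distance decay produces the neighborhood
gradient of erroneous taps — neighbors of the lead finger err most — and the
specific values were chosen so that the three distance classes separate
cleanly at the 0.5 N threshold given 2 N ± 0.35 N tap amplitudes. These
parameters are plausible settings for exercising the pipeline, **not**
estimates of any cohort; with them the paretic-like preset reproduces the
qualitative clinical picture (worse tracking error, six-fold slower release,
flattened rate slope, overflow, omissions and extra taps, a graded error
matrix) without claiming any quantitative match.

`make_cohort()` draws per-subject parameters by linearly blending the two
presets at a subject-specific severity (controls uniform on [0, 0.15],
patients on [0.3, 1]) and generates clinical scores (ARAT out of 57, Moberg
times with the > 18 s pathology flag, grip force) that co-vary with severity,
so correlation analyses have signal by construction. Sequential-task
recordings are generated on request; the default cohort simulates the three
tasks that feed the profile.

What the generator does *not* model, and what passing tests therefore cannot
show about real data: tremor-band or otherwise structured force noise (the
white-noise model makes the hold-phase CV track the noise SD, whereas real
patients showed no CV difference), motor learning within the sequential task,
amplitude–force-level interactions, fatigue and drift, and any biomechanical
coupling beyond linear amplitude enslaving.

## Profiling and statistics

The individual dexterity profile collects the six measures that discriminate
groups, each oriented so larger is worse: index-finger tracking error (ramp
and hold pooled), mean release duration, 1 − rate slope, overflow taps in the
1 Hz conditions, omission rate, and UEFTs in one-finger trials. Control norms
are per-measure mean + 2 SD thresholds; a measure is flagged pathological
only when it *strictly* exceeds its threshold, and flags are undefined
wherever the measure or norm is unavailable (a subject who skipped a task
simply has missing entries). `correlate()` (Spearman for clinical
associations, Pearson with R² for measure inter-relations) and
`group_compare()` (pooled-variance t by default — the original reporting
style does not specify Welch — with Welch available) complete the thin
statistical surface; repeated-measures ANOVA and post-hoc machinery are
deliberately left to general-purpose statistics tooling.

## Numerical conventions and verification scale

All times are seconds from task start; phase windows are half-open
[start, end); threshold crossings are linearly interpolated between samples;
analysis runs at 100 Hz. Test problem sizes: detection closure uses 500
seeded short pulse-train sessions (precision = recall = 1 against ground
truth), multi-finger scoring is checked for exact equality against a
first-principles tally over ground-truth events on 100 seeded 64-trial
sessions, sequence scoring against exhaustive subsequence enumeration for
every tap string of length ≤ 7 over the four fingers, preset separation over
200 seeds with reduced protocols (6 tracking trials, 6 taps per cued phase,
29 multi-finger trials), and profiling over a 60-subject cohort at full
protocol length (10 norm controls, 30 held-out controls, 20 high-severity
patients).

## A worked example

```{r example, eval = FALSE}
protocol <- build_tracking_protocol()
params <- ffm_preset("paretic_like", seed = 1)
sim <- simulate_tracking(protocol, params)
res <- analyze_tracking(sim$recording, protocol)
res$summary[, c("target_force", "rmse_ramp", "rmse_hold",
                "release_duration", "baseline_force")]
```

See the README for a complete control-versus-paretic profiling example with
the numbers it prints.

## Known limitations

The onset-time measures are fragile under heavy noise (see above). The
simulator's extra taps are placed in the gap after their cue, so they can
never collide with the next cue's tap — real spurious taps can. Enslaving is
instantaneous amplitude coupling; latency differences between lead and
overflow taps are not modeled, which makes the ±100 ms coincidence window
trivially satisfied in simulation. Finally, the profile thresholds inherit
the small-sample volatility of a mean + 2 SD estimate from ten controls;
with real data one would prefer quantile norms from a larger reference
sample.
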