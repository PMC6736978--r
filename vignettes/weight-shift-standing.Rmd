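---
title: "Simulating and analysing FES weight-shift standing exercise"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and analysing FES weight-shift standing exercise}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(standshift)
```

## The exercise and the measurement problem

People with complete spinal cord injury lose bone mineral density in the
lower limbs because the bones are no longer loaded through muscle action
against gravity. One therapeutic approach stands the user in an
instrumented frame and uses functional electrical stimulation (FES) of the
lower-limb muscles to drive a side-to-side weight-shift exercise: the
stimulation alternates between the left and right leg, the user leans their
upper body over the stimulated side, and for roughly five seconds most of
the body weight is carried by a single leg. Ground reaction forces are
recorded by a force plate under each foot, arm forces by instrumented
support rails, and trunk posture by a motion-capture marker on the
clavicle.

`standshift` implements the computational core of such a system offline:

* the cyclic two-group stimulation envelope and pulse-train generator,
* calibration models for the rails and plates,
* a synchronized multi-stream session container,
* a seeded virtual participant that generates complete, physically
  consistent session recordings,
* the exergame (virtual skier) feedback logic without rendering,
* the analysis pipeline (cycle segmentation from vertical GRF, conversion
  to percent body weight, lean angles and range of motion, session
  summaries), and
* repeated-measures statistics over session summaries.

Because no raw recordings of the original cohort are available, the
virtual participant doubles as the test harness: its default behavioural
profile *is* the reported group profile, and the package's acceptance
checks require the full pipeline to recover that profile from raw
simulated streams.

## The stimulation pattern

The pattern generator has four parameters: ON time, OFF time, transition
time, and the OFF-stimulation percentage. One period is
$P = t_{on} + t_{off} + 2\,t_{tr}$. A group's envelope holds a plateau at
level 1 for $t_{on}$, ramps linearly down to the OFF level over $t_{tr}$,
rests for $t_{off}$, and ramps back up; the RIGHT group is the LEFT group
delayed by $P/2$. The envelope modulates the per-channel pulse *width*
(0–500 µs); pulse amplitude (138 mA into the nominal load) and rate
(30 Hz) are fixed device constants. Ramp shape is not specified by the
hardware description; we use linear ramps and isolate the envelope in one
function so the shape can be swapped.

With the experimental setting (5 s ON, 3 s OFF, 1 s transitions) the two ON
plateaus tile the 10 s period exactly: at almost every instant exactly one
group is fully stimulated. `validate_schedule()` classifies any other
setting as `overlap` (both sides simultaneously at full level for part of
the cycle) or `gap` (instants where neither side is at full level). Note
that the *sum* of the two envelopes is not constant even in the tiling
case — while one side holds its plateau the other traverses its ramps —
so the geometry check, not a sum rule, is the tiling criterion.

```{r}
sched <- stim_schedule(on_time = 5, off_time = 3, transition_time = 1)
validate_schedule(sched)
```

Phase origin is the start of the LEFT ON plateau, which makes fixtures
deterministic. Continuous (sit-to-stand assist) stimulation is a constant
envelope; `cyclic_switch_time()` returns the next instant at which handing
over to the cyclic pattern introduces no level discontinuity.

## The session container

A recording is a set of channels on one uniform 100 Hz grid: two 6-DoF
plate wrenches, two 3-DoF rail force triplets, the clavicle marker
trajectory, and the stimulation envelope, plus an event log
(`stand_start`, `exercise_start`, `rest_start`/`rest_end`, `sit_start`)
and participant metadata. Timestamps are seconds from session start; the
transport-layer clocks of the original acquisition software are abstracted
away for offline reproducibility. Multi-rate inputs are aligned with
`synchronize()`, which resamples (linear interpolation, never
extrapolation) onto the intersection of the stream spans. On disk a
session is a directory of one CSV per stream plus a JSON sidecar —
entirely plain text, inspectable and diff-able; round-trips preserve
values to at least six decimals.

## The virtual participant

The simulator replaces the human and the hardware, not with a
musculoskeletal model but with a behavioural one: the paper-level
description of the exercise (forces and angles, not dynamics) is encoded
directly.

* **Force balance.** At every sample, before noise,
  $F_{z,\mathrm{left}} + F_{z,\mathrm{right}} + F_{z,\mathrm{arms}} +
  F_{z,\mathrm{residual}} = m g$ with $g = 9.81$ m/s². The arms carry a
  constant fraction (default 7.59 % BW in total, sign per push/pull
  strategy), the knee pad/harness a residual fraction, and the legs split
  the remainder.
* **Residual support.** The residual share is not reported anywhere; we
  fix it at 2.42 % BW (within the 3 % cap we impose) so that the two legs
  together carry 90 % BW at plateau, matching the reported total
  leg loading of approximately 90 % BW. This is the one simulator fraction
  chosen by closure of the force balance rather than taken from a printed
  number.
* **Lean dynamics.** The lean drive is the normalized envelope difference
  of the two stimulation groups; the realized drive is a first-order lag
  (default time constant 0.4 s) of that target — the human tracks the
  stimulation with the exergame's guidance but not instantaneously. At a
  mature plateau the supporting leg carries `mature_support_frac`
  (default 0.7532 of BW).
* **Habituation.** Within a session, the achievable peak support ramps
  from `habituation_start` (default 0.3) times the session level up to the
  full level over the first 300 s of exercise, and the lean amplitude is
  floored so the participant never leans away from the stimulated side.
  Early peaks therefore sit below the 50 % BW detection threshold and are
  not counted, reproducing the reported ~650–700 countable cycles per
  60-min session.
* **Longitudinal improvement.** `participant_profile()` is a
  hold–ramp–hold curve: sessions 1–5 at the early value (default 0.6369),
  sessions ≥ 8 at the late value (default 0.7861), linear in between. The
  shape satisfies both boundary requirements (session 1 equals the early
  value; saturation at the late value; monotone) *and* makes the
  first-five/last-five group means of a 12-session series equal the
  configured early/late values exactly. The sway half-angle follows the
  same shape (defaults 6.065° early, 7.61° late, i.e. half the reported
  12.13°/15.22° ranges of motion).
* **Posture.** The clavicle marker sits `clavicle_height` (default
  1.35 m) above the plate surface and translates laterally by
  $h \tan\theta$, with $\theta$ proportional to the realized weight shift
  up to the session's sway half-angle.
* **Noise.** Additive Gaussian noise is applied last: 5 N SD on force
  channels, 0.5 N·m on plate moments, 2 mm on marker coordinates. These
  magnitudes are not reported for the original sensors; they are chosen
  small relative to the signals (a plateau is ~500–600 N) but large enough
  that detection and averaging are genuinely exercised.

### Peak-statistic calibration

The analysis pipeline defines a cycle's load as the *maximum* of the raw
vertical force during the cycle. On a noisy plateau of a few hundred
samples the expected maximum exceeds the plateau level by
$\sigma\,\mathrm{E}[\max_n Z]$ (about 14 N, i.e. 1.7–2.6 % BW depending on
body mass, at $\sigma = 5$ N). Since the participant's configured fractions
are defined as *pipeline-recovered* quantities, `simulate_session()`
computes this bias analytically at run time — $n$ is counted from the
deterministic cycle shape as the samples within one noise SD of the cycle
maximum, and $\mathrm{E}[\max_n Z]$ by numerical integration — and lowers
the target plateau by exactly that amount. The expected detected peak then
equals the configured fraction; with zero noise the correction vanishes
identically. Without this calibration every recovered support fraction
would be biased upward by the noise-maximum effect, which is a property of
the peak statistic, not of the participant.

### What the simulator does not model

Fatigue (none was observed in the reference cohort), balance-loss events,
sit-to-stand mechanics beyond threshold envelopes, electrode–tissue
electrophysiology, the 49 non-clavicle markers of the full capture set,
and any drift between sensor clocks. Passing recovery tests therefore
shows that the *pipeline* is correct and internally consistent with the
simulator's assumptions — it does not validate those assumptions against
real human data.

## The analysis pipeline

Cycle segmentation follows the published rules exactly: strict local
maxima of the raw vertical plate force, amplitude at least 50 % of body
weight, and at least 5 s between retained peaks. Conflicts within the
separation window are resolved by keeping the larger peak (greedy in
descending amplitude); the original study's manual visual inspection step
is replaced by two deterministic rules — peaks inside labelled
transfer/rest intervals are dropped, and peaks whose separation window is
truncated by the recording boundary are dropped — because an automated
pipeline must be reproducible. Flat-topped maxima report their first
sample. The 5 s separation is applied per plate: opposite-side peaks are
by design about 5 s apart and would otherwise collide with the criterion.

Forces at each peak are read from all co-recorded streams (grid sample, or
linear interpolation off-grid) and converted to percent body weight by
$100 F/(m g)$, preserving sign so that a pull on the rails stays negative;
arm support is reported as the sum of the two rails' vertical-force
magnitudes. The lean angle is the two-argument arctangent of the
clavicle's lateral displacement from its reference over its height above
the plate surface; the reference is the mean clavicle position during the
centered phase between `stand_start` and the first detected peak (a
per-cycle-start reference is available as an option). Range of motion sums
the absolute angles of successive opposite-side cycle pairs,
non-overlapping, dropping a trailing unpaired cycle.

Session summaries report cycle counts, per-side and overall peak %BW,
arm %BW, ROM, and the within-session profile of peak %BW versus cycle
index; when a habituation duration is supplied, post-habituation
aggregates are reported alongside the all-cycle values. Longitudinal
comparisons use the post-habituation session means, since the quantities
being tracked are defined on the stabilized part of the session.

## Statistics

`rm_anova()` is the one-way within-subject decomposition
($F = MS_{cond}/MS_{err}$ on $(k-1, (k-1)(n-1))$ degrees of freedom,
no sphericity correction, matching the reported uncorrected df), fitted
via `stats::aov` with an `Error(subject)` stratum and cross-checked in the
tests against an independent sums-of-squares implementation.
`tukey_hsd()` computes studentized-range statistics and p-values via
`stats::ptukey`, validated against direct numerical integration of the
range distribution. `compare_periods()` builds the participants ×
(first five + last five sessions) table, runs the omnibus test over the
ten session slots, and applies the Tukey comparison to the early/late
grouped means using the ANOVA's error mean square.

One aggregation subtlety is deliberately surfaced: for a complete table
the mean per-participant early-to-late difference algebraically equals the
difference of group means, so the two printed aggregations of the
reference study (14.92 vs 13.88 points) cannot both be reproduced by any
complete-data simulation. `compare_periods()` reports both quantities
under distinct names (`group_diff`, `mean_participant_diff`) and the
simulator's defaults reproduce the group means, leaving the difference at
~14.9 points.

## Numerical choices and problem sizes

* Resampling and peak-time sampling use linear interpolation; no
  extrapolation anywhere.
* Peak ties in amplitude are broken toward the earlier peak; simultaneous
  bilateral peaks resolve to the larger.
* The first-order lag is discretized as
  $d_{k} = d_{k-1} + \alpha\,(u_k - d_{k-1})$ with
  $\alpha = \Delta t/(\tau + \Delta t)$.
* p-values print truncated at four decimals, flooring at "< 0.0001".
* The test suite simulates 10–25 min sessions (the per-session estimates
  it checks are duration-independent) and one full 60-min session for the
  cycle-count check; the acceptance script simulates everything at the
  full 60-min, 100 Hz scale — 45 sessions in roughly a minute on one core.

## Worked example

```{r, eval = FALSE}
p <- virtual_participant(body_mass = 83.3)
rec <- simulate_session(p, sim_config(seed = 1, duration = 3600))
cycles <- analyze_session(rec)
summ <- summarize_session(rec, cycles, mature_after = p$habituation + 10)
summ$cycle_count          # ~687 countable cycles
summ$peak_bw_mature       # ~75 %BW on the supporting leg after habituation
summ$arm_bw               # ~7.6 %BW through the rails
mean(range_of_motion(cycles))   # ~12 degrees side-to-side
```

## Known limitations

The simulator's behavioural realism is bounded by what the reference
study reports: inter-cycle variability, asymmetries between left and right
leans, and session-to-session scatter beyond the improvement trend are
minimal in simulated data, so between-group standard deviations and
F statistics of the original cohort are *not* recovery targets — the
statistics module is validated by oracle equivalence and type-I
calibration instead. The exergame's control law and scoring constants are
implementation choices (imbalance target ±0.5, band 0.25, 10 % BW arm
threshold) consistent with, but not dictated by, the published game
description.
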