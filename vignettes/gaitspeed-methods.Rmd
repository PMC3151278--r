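---
title: "Estimating walking speed from waist-worn accelerometry: models, simulator and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating walking speed from waist-worn accelerometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaitspeed)
```

## Scope and data model

`gaitspeed` estimates walking speed from a single waist-worn tri-axial
accelerometer sampled at 100 Hz and validates the estimates against a 1 Hz
reference speed trace. The channel convention is `x` vertical, `y`
antero-posterior, `z` medio-lateral; samples are held in m/s² internally
(readers convert from g with a fixed factor of 9.81). Per-step quantities
are attached to half-open sample intervals `[start, end)` with 1-based
start indices, the natural R translation of half-open slicing.

The pipeline is: inactivity detection and stream synchronization →
boundary trimming → step detection → per-step feature extraction → twelve
speed estimators → agreement statistics.

## Pre-processing

**Inactivity detection.** Protocol sessions embed 15 s rest gaps between
activity levels. Rests are found as maximal intervals where the 1 s
moving RMS of the gravity-free energy channel
$e_i = \sqrt{x_i^2 + y_i^2 + z_i^2}$ stays below 0.5 m/s² for at least 5 s.
The 0.5 m/s² default separates the simulator's rest noise
(≈0.09 m/s² RMS) from its slowest walking bout (≈0.8 m/s² RMS) with a wide
margin on both sides; channel medians are subtracted first so the detector
is indifferent to whether the vertical channel carries the static gravity
component.

**Synchronization.** Both streams are reduced to binary activity profiles
on a 1 s grid (accelerometer: per-second energy RMS above threshold;
trace: speed above 0.05 m/s) and the integer lag maximizing their
agreement over ±60 s is returned, ties broken toward zero. This works
whenever the rest/activity pattern is aperiodic within the search window;
a protocol whose levels and rests repeat with a fixed period is
intrinsically ambiguous for any profile-alignment method, which is why the
package's synchronization checks use unequal level durations.

**Boundary trimming.** Gait initiation and termination contaminate the
first and last seconds of each bout, so 5 s are cut from both ends of
every aligned segment before analysis; a 90 s protocol level therefore
contributes 80 s.

**Zero-phase filtering.** Drift correction uses a fourth-order low-pass
Butterworth at 0.1 Hz applied forward–backward (zero phase, so step timing
is untouched). At this cutoff the filter poles sit very close to the unit
circle and naive forward–backward filtering has edge transients spanning
the whole signal; the implementation therefore demeans the input and
extends it by odd reflection over 3/cutoff seconds at both ends before
filtering, which makes the DC gain exactly 1 and confines transients to
the padding. The effective magnitude response is the squared Butterworth
magnitude $(1 + (f/f_c)^8)^{-1}$, verified in the tests against that
closed form.

## Step detection and features

A bout is first classified as walking or running from the RMS of its
demeaned vertical channel (threshold 3.5 m/s²); class-specific peak
thresholds and refractory delays are then applied to the lightly smoothed
(0.1 s moving average) vertical channel: walking 0.5 m/s² above the bout
mean with a 0.30 s delay, running 2.5 m/s² with 0.20 s. The walking
threshold is set at 0.5 m/s² because the clean vertical-acceleration
amplitude of slow walking under the pendulum geometry,
$(h/2)(2\pi f)^2$, falls below 1 m/s² for cadences under about 80
steps/min — a threshold of 1 m/s² would miss slow walking entirely.
Each detected peak is one step; the spans between consecutive peaks form
the step intervals on which features are computed (n peaks yield n−1
interval rows; counting algorithms use the peak count).

Per step, ten features are computed on each of the four channels
(`x`, `y`, `z`, energy `e`): minimum, maximum, mean, sum, sum of absolute
values, range, RMS, maximum−mean, step amplitude, and min/max amplitude
duration; the step duration is added once, for 41 features. Two feature
definitions are not fully standardized in the field and are implemented as
explicit choices: *step amplitude* is the channel maximum minus the
preceding trough within the step (distinct from range and from
maximum−mean), and *min/max amplitude duration* is the signed time from
the channel minimum to its maximum. The latter is used by none of the
shipped models and exists for completeness of the 41-feature set.

## The twelve estimators

*Step length (default)* multiplies the step count by a configured walking
step length; *walk/run* adds a second, running step length, selected by
the bout's gait class. *Step length (pendulum)* inverts the
inverted-pendulum geometry per step: the vertical excursion $h$ is
obtained by double integration of the drift-corrected vertical channel
over the step, and $d = k \cdot 2\sqrt{2Lh - h^2}$ with leg length $L$.
Two numerical details matter: the unknown initial velocity at the step
boundary appears as a linear ramp in the doubly integrated displacement
and is removed by linear detrending before the excursion is read off; and
steps with degenerate excursions ($h \le 0$ or $h \ge L$) are skipped and
counted rather than propagated. The correction factor defaults to
$k = 1$ (the literature uses values up to ≈1.25; it is a configurable
calibration constant).

*Walk ratio (default)* exploits the near-constancy of the ratio
$w = d/C$ between step length (m) and cadence (steps/min) across walking
speeds: $v = w\,C^2/60$, with the conventional population value
$w = 0.0065$. *Walk ratio (calibrated)* replaces the universal $w$ with an
individual value derived from one bout of known speed — in the standard
protocol, the normal-walking level, mirroring the original study design
(which also noted that this gives the calibrated variant an in-sample
advantage on that protocol).

*LR/SVR models* regress per-step speed on fixed feature subsets: the
MA-model on maximum−mean of the vertical channel alone; the C-model on a
13-feature subset; the energy-model on the sum of absolute values of each
axis plus mean energy (a biomechanically motivated set connected to
energy-expenditure estimation); the RBWE-model on a 5-feature subset.
Features are z-scored with parameters stored in the model; SVR uses a
radial kernel with shipped hyperparameters (MA: C=100, γ=0.03, ε=0.2;
C: C=5, γ=0.0024, ε=0.01; energy: C=64, γ=0.004, ε=0.00049) found by
10-fold cross-validated grid search in the original development; a seeded
grid-search utility and a greedy backward-selection utility are provided
for re-derivation. Per-step training targets are the mean reference speed
over each step's span (linearly interpolated between the 1 Hz samples);
interval estimates are step-duration-weighted means of per-step
predictions, with negative raw predictions clipped to zero and counted.

*Integration* recovers speed from the antero-posterior channel: the
channel is drift-corrected (0.1 Hz low-pass subtraction), integrated by
cumulative trapezoids, and the residual integration drift is removed from
the velocity with the same low-pass subtraction. Around steady walking
the forward velocity oscillates about the mean speed with amplitude equal
to that speed, so each 1 s bin's speed is estimated as the oscillation
amplitude $\sqrt{2}\,\mathrm{RMS}$ — an estimator invariant to the
arbitrary gait phase at the segment start, unlike the mean of the
integrated velocity, which scales with the cosine of that phase. Bins are
combined by median because the detrending filter settles over roughly
10 s at each segment end and those boundary bins would otherwise bias a
mean.

## Agreement statistics

CCC uses population (1/n) moments (Lin's original estimator; an n−1
variant is available as a switch). Two identical constant series are
defined to agree perfectly (CCC 1); two unequal constant series give CCC 0
with a warning. CP compares $|a_i-b_i| \le \delta$ with a 1e-9 absolute
guard so representation error cannot flip boundary cases. LOA is
bias ± 1.96 × sample SD of the differences. Confidence intervals use a
cluster (subject-level) percentile bootstrap with 2000 resamples by
default, seeded; subject-level resampling is the defensible default
because intervals within a subject are dependent. CP intervals are clipped
to [0, 1]. The evaluation pairs one trimmed speed interval with its
interval-mean reference (the granularity of the per-level validation
figures); per-second pairing can be assembled from the same primitives if
needed.

The ranking report sorts algorithms by CP1 (ties by CCC) and carries
CP1–CP3 and CCC, each with its CI, plus the LOA triple — the structure of
a method-comparison ranking table.

## The simulator: what it emulates, and what it does not

Sessions are built from per-step waveform blocks satisfying the pendulum
geometry: the vertical channel is the exact second derivative of a
centre-of-mass path with peak-to-peak excursion
$h = L - \sqrt{L^2 - d^2/4}$, with its single peak at mid-step so bout
edges are troughs and the peak count equals the step count on clean
signals. The antero-posterior channel is a zero-mean oscillation at the
step frequency whose amplitude, $2\pi f \cdot (f d)$, is chosen so its
time integral oscillates with amplitude equal to the true speed — the
property the integration estimator relies on. The medio-lateral channel
alternates at the stride frequency $f/2$.

A target speed $v$ is split into cadence and step length through the
walk-ratio prior ($d = \sqrt{60\,v\,w}$), switching to a capped step
length (default 1.0 m) for running; the gait class is "run" when the cap
engages or $v \ge 2.3$ m/s. Per-step lengths are jittered (SD 3% of $d$,
a modelling choice — no within-level fluctuation model is available from
the study), step durations are quantized to whole samples, and the step
length is then recomputed so every step's true speed is exactly the level
speed; the 1 Hz reference trace is exact by construction. Defaults
reproduce the study conditions: five levels at 0.65/1.11/1.47/1.83/2.70
m/s of 90 s each, 15 s rests (plus lead-in/lead-out), activity noise
SD 0.3 m/s², rest noise SD 0.05 m/s². An outdoor mode walks 812 m with a
piecewise-linear speed profile peaking at half distance. Training cohorts
draw the walk ratio uniformly from [0.0055, 0.0075] m/(steps/min), leg
length from [0.8, 1.05] m and the running step-length cap from
[0.95, 1.10] m, emulating inter-subject variability.

What the simulator does **not** model — and hence what green tests do not
establish about real recordings: ground-reaction-force waveform detail,
within-step speed fluctuation, arm-swing and posture artefacts, sensor
tilt and axis misalignment, pathological or asymmetric gait, and surface
or footwear effects. Because the generator is pendulum-consistent and
walk-ratio-consistent by construction, the pendulum and walk-ratio
estimators perform better here than on field data; the end-to-end checks
validate the machinery (detection, features, training, prediction,
statistics), not field accuracy.

## Numerical and design choices

- Gravity is excluded from emitted signals by default; an option adds the
  constant 9.81 m/s² on the vertical channel, and all detectors are
  offset-robust so both conventions are handled.
- Whether the 0.1 Hz low-pass output is used directly or subtracted was
  left open in the source material; it is used here as the *drift
  estimate* and subtracted (high-pass detrending), which is the only
  reading under which integration of an oscillatory channel is
  meaningful.
- Grid-search tie-breaks go toward smaller C, then smaller γ, then
  smaller ε (less complex models first); fold assignment is seeded.
  Grid points whose SVR degenerates (ε wider than the target range)
  score infinite CV error instead of aborting the search.
- The RBWE-model is implemented as a linear regression over its published
  feature column; no SVR hyperparameters exist for it, so generic
  defaults are supplied if an SVR variant is requested.
- The MA-model's single feature (maximum−mean, vertical) is treated as
  included (its column marking is ambiguous in the source table).
- Seeds: every randomized operation runs under a locally seeded RNG that
  restores the caller's state; pipeline stages derive their seeds from
  the master seed by a counter scheme so single stages can be re-run
  reproducibly.

## Problem sizes

The shipped validation experiment trains on 15 simulated subjects and
evaluates on 17 held-out subjects under the full five-level indoor
protocol (about 750 steps per session), with the pooled training set
thinned to at most 6000 steps — sizes chosen to mirror the study cohorts
while keeping a complete run in the order of a minute on one CPU.
Synchronization checks use 100 sessions with random lags in ±30 s on a
two-level protocol with unequal level durations; bootstrap checks use
2000 resamples.

## Known limitations

- The step detector assumes one gait class per analyzed bout; segments
  mixing walking and running within one contiguous interval get a single
  class.
- Synchronization is integer-second and requires an aperiodic
  activity/rest pattern within the lag search window.
- The integration estimator assumes near-sinusoidal velocity oscillation;
  it is a poor estimator for highly irregular gait.
- Bootstrap percentile intervals with few clusters (say, under 20
  subjects) are known to undercover slightly; interpret 95% CIs on small
  cohorts accordingly.
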