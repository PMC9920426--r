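---
title: "Wrist-based fall detection: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Wrist-based fall detection: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wristfall)
```

## The problem

A fall detector running on a wrist-worn device reads a triaxial
accelerometer (and optionally gyroscope and orientation sensors) at 50 Hz
and must decide, window by window, whether the wearer has fallen.  Fall
detection is a binary classification problem with a strong asymmetry: a
missed fall (false negative) can leave an injured person without help, while
a false alarm merely annoys.  The device imposes hard constraints — little
RAM, no multithreading, a small battery — so feature collection and
classification run *sequentially*: while the classifier runs, no samples can
be collected.

`wristfall` implements both halves of the workflow:

* an **offline study pipeline** — synthetic data generation, frequency
  reduction, sliding-window labeling, the FS-1 feature set, and stratified
  5-fold cross-validation over an exhaustive configuration grid — used to
  pick the deployed configuration; and
* an **online detector simulator** that reproduces the on-device cycle:
  recursive feature updates, a classification dead zone, a memory-capped
  dataset and a user-feedback learning loop.

## Windows, labels and features

Recordings are cut into sliding windows `[start, start + w)` with stride
`jump_s` (default 1 s).  A window from an ADL (activity-of-daily-living)
file is always labeled ADL.  A window from a fall file is labeled **Fall**
iff it overlaps at least 50% of the manually delimited *actual fall*
interval — the roughly 3.1 s span containing the fall's four phases
(prefall, impact, adjustment, postfall):

$$\text{label} = \text{Fall} \iff |[s, s+w) \cap [a,b]| \ge \tfrac12 (b-a).$$

Two conventions the arithmetic relies on: the 50% threshold is measured
against the *fall* duration, not the window, and a tie (exactly 50%) counts
as Fall — the safety-first reading of "at least".  Window `[t, t+w)` holds
the samples with index $t f \le i < (t+w) f$, so a 9 s window at 50 Hz holds
exactly 450 samples.  Samples after the last full window are discarded.

The FS-1 feature set is the per-axis maximum, minimum, arithmetic mean and
sample variance ($N-1$ denominator).  With 4 statistics, 3 axes and 3
sensors the full pool has 12 *(sensor, statistic)* elements, each applied
jointly to x, y, z; all $2^{12}-1 = 4095$ non-empty subsets enter the grid.
No feature scaling is applied anywhere: the on-watch kNN runs on raw
features, so the offline study must too.

### Streaming statistics

On the device the window is never buffered; statistics update per reading.
Max and min replace-or-keep; the mean moves by
$(x_N - \bar{x}_{N-1})/N$; the running sample variance uses the
Welford-type recurrence

$$s^2_N = s^2_{N-1} + \frac{(x_N-\bar x_{N-1})(x_N-\bar x_N) - s^2_{N-1}}{N-1},$$

which keeps `stream_finalize()` exactly equal (to float noise, < 1e-9) to
the batch computation at every $N$ — the module's central property test
feeds thousands of random windows through both paths.

## The classifier and the evaluation grid

The deployed detector is a from-scratch kNN with Euclidean distance,
$k = 3$, chosen as the best odd-$k$ configuration (odd $k$ avoids vote
ties; where a tie can still occur, e.g. even $k$ in the grid, the
prediction is Fall — again safety-first).  Distance ties at the k-th
neighbour are broken by training-point insertion order, for bitwise
reproducibility.  SVM (radial and polynomial kernels, via `e1071`) and
decision trees (Gini/entropy/log-loss splits, via `rpart`; entropy and log
loss are the same information criterion and are kept as distinct grid
entries) are adapters used only by the grid harness — the on-device detector
is kNN-only.

The grid spans 5 frequencies (50, 40, 25, 10, 5 Hz), 5 window sizes (5–9 s),
15 algorithm variants and 4095 feature subsets:
$5 \times 5 \times 15 \times 4095 = 1{,}535{,}625$ configurations.  Counting
is always exact; evaluation supports a seeded random subsample (`budget`)
because the full grid at real-data scale exceeds desk scale.  Feature tables
are cached per (frequency, window) pair so classifiers re-use them.

Cross-validation is stratified by window and seeded.  The fold assignment
ignores which recording a window came from, matching the apparent offline
protocol; a `group_by_recording` style split was considered and rejected as
a default because the reference protocol gives no indication of grouping —
leakage-free evaluation can be had by filtering the feature table by
recording metadata before splitting.  Frequency reduction uses linear
interpolation onto a uniform grid (deterministic, handles the non-integer
50→40 ratio, introduces no new extrema); a median-of-segment mode exists for
sensitivity checks.  The rolling median filter is centre-aligned with
passthrough edges, so trace lengths (and the 450-sample arithmetic) are
preserved.  Vertical acceleration rotates the body-frame accelerometer
vector by the orientation quaternion (scalar-first, body-to-world — the
convention is fixed in a single function) and takes the world z component.

## The synthetic generator

The generator exists so that every downstream stage is testable without the
real dataset.  It emulates the acquisition protocol: 14 young participants
(YP), falls F01–F08 and ADLs D01–D11, three repetitions each (four for
F08) — 350 fall and 462 ADL signals; 11 elder participants (EP) performing a
safe ADL subset with lower amplitudes and cadence.  Files last 8–16.5 s.
Fall files embed a four-phase fall whose duration is drawn from
Normal(3.1037, 0.2731) s truncated below at 1.5 s, with the impact spike
cluster at the interval midpoint, a decaying adjustment oscillation, and a
postfall segment whose body-frame gravity is derived from the lying
orientation quaternion, so orientation and accelerometer stay consistent at
rest.  ADLs come in four families: periodic (walking 2 Hz, jogging 2.8 Hz,
stairs 1.7 Hz), transitional (sit/stand bumps), impulsive (hits at
18 m/s², claps at 20 m/s² — deliberately fall-confusable), and quasi-static
(door handling).  All fundamentals stay at or below 20 Hz, the maximum
frequency of human movement.

Values the reference protocol does not state are calibration choices made
once: additive Gaussian noise of 0.3 m/s² per axis, a 30 m/s² fall impact
peak, ±15% per-user amplitude jitter (so users differ more than repetitions,
mirroring the participant bias of acted datasets), and EP scaling of 0.6 on
amplitude and 0.85 on cadence.

**What passing tests do and do not show.**  The generator preserves the
discriminative structure FS-1 relies on (falls have extreme max/min, large
variance, and a postfall mean shift from lying), so the deployed
configuration reaches ≥ 0.99 cross-validated accuracy on synthetic data,
comfortably above the 0.90 gate, and accuracy degrades as frequency drops
to 5 Hz.  It does **not** reproduce real per-user idiosyncrasies or
within-user variance; in particular, personalised (single-user) models on
synthetic data are essentially perfect with zero fold-to-fold spread, so the
field observation that the all-users model is roughly ten times *more*
stable than personalised models cannot be reproduced here — the package
exposes the comparison (`personalised_eval()`), and only real data can
decide it.  Equally, exact published table values require the real dataset
and are out of scope for automated checks.

## The online simulator

`run_detector()` reproduces the device cycle.  Collect `window_s` seconds of
samples through `stream_update()`; classify; during classification the
device is deaf — the dead zone.  The dead-time model is linear in dataset
size, `detect_cost_s_per_point = 2/650` s per stored point by default,
calibrated to the single field observation of roughly 2 s at about 650
points (the device gives no timing model; the constant is a config knob, and
a fixed-cost override exists for arithmetic checks).  Over 60 s with zero
dead time a 6 s window is classified 10 times and a 9 s window 6 times; at
2 s of dead time the 9 s cycle stretches to 11 s and only 5 calls fit.  A
ground-truth fall wholly inside a dead zone is unreachable and reported in
`falls_missed_in_dead`.

On a Fall prediction the simulator queries the feedback oracle and appends
the window's features with the answered label (provenance
`"user-feedback"`).  An unanswered query counts as a confirmed fall —
fail-safe, since silence may mean the wearer cannot answer.  The dataset is
capped (default 400 points, the deployed 200 fall + 200 ADL seed);
`prune_dataset()` removes, in order, the oldest seed ADLs, then the oldest
seed falls, then the oldest feedback points — mirroring the on-watch pruning
episode in which the 200 seed ADLs plus 50 more seed points were deleted
before any feedback data — while deferring removals that would push the
class ratio beyond `balance_ratio_max` (default 3) when a later candidate
avoids it.  Collection restarts immediately after classification; a feedback
pause is not modelled (the reference behaviour is unstated).

`power_budget()` performs the battery chain: draws are capacity/lifetime
rounded to 3 decimals (matching the printed precision of the field
arithmetic), so (1.02 Wh, 34 h, 144 h) gives 0.03 and 0.007 W, a 0.023 W
delta and 0.552 Wh per day.

## Numerical choices and degenerate inputs

* Durations are defined as `samples / rate`, so a 16.5 s file at 50 Hz holds
  exactly 825 samples and the window count `floor((d - w)/jump) + 1` is
  exact (with a 1e-9 tolerance absorbing float representation of 0.1 s
  grids).
* Empty windows error; single-sample windows have variance 0; metrics with
  zero denominators return `NA` rather than propagating NaN.
* A missing sensor file is a structured marker on the recording, not a
  failure; a malformed CSV cell fails loudly with the file and line.
* CSVs are written at full double precision (`%.17g`) so write→read is the
  identity.
* Seeds: every stochastic function takes an explicit seed and restores the
  caller's RNG state; derived child seeds stay below 2³¹.

## Problem sizes used by the test suite

The package's own checks run on generated data at the protocol's scale: the
end-to-end check generates the full 812-recording YP protocol (about 3,000
nine-second windows) and cross-validates at 50 Hz and 5 Hz over five seeds;
the streaming-equals-batch property uses 1,000 random windows of 1–450
samples; the kNN oracle comparison uses 500 random instances with up to 200
points and 12 dimensions.  Unit tests use a 12-recording miniature protocol.

## Known limitations

* The generator is phenomenological, not biomechanical; it supports
  pipeline validation, not clinical claims.
* Real-data table values (and the longitudinal field results of the
  learning version) are reproducible only with the real dataset; the
  package reads its per-sensor CSV layout via the layout descriptor in
  `default_layout()`.
* The EP cohort's published total of 157 signals reflects repetition counts
  that varied per volunteer; it is carried as protocol metadata and never
  recomputed.
* The dead-time model is linear with a single calibration point; real
  devices will deviate.
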