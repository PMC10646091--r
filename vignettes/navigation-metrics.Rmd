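---
title: "Quantifying memory-guided navigation in a virtual water maze"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying memory-guided navigation in a virtual water maze}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mazemetrics)
```

## The task and its data

A virtual Morris water maze presents a circular arena (radius 3.8 virtual
meters) surrounded by distal landmarks. Navigation unfolds in blocks: three
learning trials from a fixed start, in which the target object becomes
visible when approached (registered as found within 0.8 m), followed by
four probe trials whose start positions are the learning start rotated by
0, 90, 180 and 270° about the arena center; the target stays hidden and the
navigator indicates its remembered location by button press. The recording
is a per-trial time series of timestamps, (x, y) position and orientation —
yaw directly, or quaternions converted on load — sampled at the display
refresh rate (60 Hz for a stationary desktop setup, 90 Hz for a mobile,
head-mounted one); translation speed is 1.4 m/s.

`mazemetrics` turns these time series into eight per-trial metrics plus two
grid maps, aggregates them to participant and group × setup summaries, and
ships a navigator simulator that reproduces the task geometry so every
metric can be validated end to end against known ground truth.

## The metrics and their assumptions

**Memory score.** The response-to-target distance is ranked against
`n_reference = 1000` locations drawn uniformly over the arena disk
(`r = R√u`, angle uniform — uniform in area, respecting the circular
boundary). The score is `100 − 100·(fraction of reference points strictly
closer to the target)`; 50 is chance, and scores below 50 indicate a bias
away from the target. Two conventions are fixed here and worth stating:

* *Strict inequality.* Reference points at exactly the response distance do
  not count against the score. With continuous coordinates ties have
  probability zero; the convention only matters for the degenerate
  perfect-response case, which scores exactly 100.
* *Per-trial reference draws.* Each trial's 1000 points are drawn from a
  seed derived from (global seed, participant, setup, block, trial), so
  results are reproducible yet uncorrelated across trials.

The Monte-Carlo score estimates `100·(1 − A∩/(πR²))`, where `A∩` is the
area of the disk of radius `|final − target|` centered on the target
intersected with the arena. `memory_score_analytic()` evaluates this
closed form (lens formula with containment limits); the test suite holds
the Monte-Carlo estimate to within three binomial standard errors of it
across random configurations.

**Scatter.** The mean of the `choose(4, 2) = 6` pairwise distances among a
block's probe responses. The default unit is meters; a
normalize-by-diameter option yields a dimensionless relative scatter, since
published values of this statistic are sometimes reported relative to the
arena size.

**Latency, path length, path error.** Latency is last minus first
timestamp. Path error relates the traveled polyline length to the straight
start→final segment (`100·(actual − ideal)/ideal`). Trials whose start and
final position coincide (immediate button press) have no defined ideal
path; they yield `NA` rather than infinity and are flagged.

**Surface coverage.** The implemented formula is the bounding-box
expression with *full* widths, `100·π·w·h/(πR²)`; a path spanning the whole
bounding square therefore evaluates to 400%. An inscribed-ellipse variant
with semi-axes (`semi_axes = TRUE`, maximum 100% for that square) is
provided, but the full-width form is the default because it is the form the
statistic is defined in; as a monotone rescaling it ranks trials
identically.

**idPhi (initial angular velocity).** Yaw is unwrapped (consecutive
differences mapped into (−π, π]) and then low-pass filtered at 6 Hz so only
head/view rotations at a behaviorally relevant time scale survive. The
statistic is the mean |Δyaw| per sample over the first 5 s of the trial —
the window in which a navigator scanning the landmarks for self-
localization shows elevated angular motion. Two choices are deliberate:

* *Filter design.* Only the cutoff is inherent to the statistic; the
  implementation uses a 4th-order Butterworth applied forward–backward
  (zero phase), the standard choice for kinematic signals, so that filter
  delay cannot shift rotation onsets into or out of the window. The
  endpoint-to-endpoint linear trend is passed through untouched (it is
  DC-like) and only the residual is filtered, over odd-reflection padding
  of one warm-up length (3·fs/cutoff samples); constants and ramps are
  reproduced to machine precision and edge transients are suppressed.
  Sequences too short to filter, and sampling rates at or below twice the
  cutoff, fall back to the unfiltered signal with a warning and a
  `filtered = FALSE` attribute.
* *Units.* The printed formula divides the summed |Δyaw| by the number of
  differences, so the raw unit is radians per sample step and depends on
  the sampling rate; `per_second = TRUE` multiplies by the rate when
  comparing across 60 and 90 Hz setups. Both variants are exposed; the
  per-step form is the default and is what the pipeline records.
* *Order of operations.* Unwrap, then filter. Filtering a wrapped angle
  channel would smear the ±π discontinuities into spurious rotation.

**Trajectory distance (path replication).** Both trajectories are rotated
about the arena center so their first samples land on the canonical ray
(angle 0, radius preserved) — using each trajectory's *measured* start
angle, not the designed rotation, so the operation applies to arbitrary
data — and compared by dynamic time warping with squared-Euclidean local
cost, unit-weight steps {(1,0), (0,1), (1,1)}, and full boundary
alignment. The reported value is `√(cost / max(m, n))`: the minimal
admissible warping path visits `max(m, n)` cells, so this normalization
removes the dependence on recording length without resampling — the point
of DTW here is alignment regardless of path length. The DTW recursion is
implemented in C++ (an `m × n` dynamic program; a cost-only variant with
O(min(m, n)) memory is used in the pipeline); tests verify it against
exhaustive enumeration of all warping paths and an independent top-down
recursion for all `m, n ≤ 7`. Windowed (Sakoe–Chiba) and open-ended
variants are out of scope.

## The synthetic navigators

The simulator reproduces the study conditions as its defaults: 6 blocks ×
(3 learning + 4 probe) trials; start axes at 0–300° in 60° steps; targets
on a quadrant center axis ±45°/±135° relative to the start at a center
distance uniform in [0.2, 0.8]·R; probe rotations a permutation of
0/90/180/270°; speed 1.4 m/s; capture radius 0.8 m; 60/90 Hz sampling; and
a rotation rate of 50°/s (the stationary setup's value, adopted for both
setups since no analog is defined for physical turning).

Three policies span the behavioral modes the metrics are meant to
dissociate:

* **direct** — scan in place for `scan_duration` seconds (a triangular yaw
  sweep at `scan_rate` that returns to the initial heading), then walk
  toward a goal estimate: the true target on learning trials (where the
  object reveals itself), the target plus isotropic Gaussian noise
  (`goal_noise_sigma`) on probes. The recorded yaw turns toward the
  movement bearing at the rate-limited rotation speed, so the yaw channel
  is continuous and angular motion accumulates with scan time. Probe trials
  end with the final sample at the goal estimate — the button press at the
  remembered location — which makes the noiseless agent score exactly 100.
* **random_search** — a correlated random walk with specular reflection at
  the wall; learning trials end at the capture radius, probes at
  `max_duration` (default 30 s, matching observed human probe latencies in
  such tasks).
* **path_replication** — egocentric replay: the displacement sequence of
  the block's last learning trial is reproduced relative to the rotated
  start's facing direction, i.e. *without* compensating for the probe
  rotation. On a 180° probe the replayed endpoint is the point reflection
  of the learned final through the center, which drives the memory score
  below 50 — exactly the error pattern that distinguishes route replay
  from allocentric navigation. Learning trials for this policy run the
  direct policy (the route must first be acquired).

Default noise levels (`goal_noise_sigma = 0.6` m, `heading_noise_sigma =
0.05` rad/step, `scan_duration = 2` s) were chosen once to land the
simulated metric distributions in the empirically plausible range for
healthy navigators (memory scores in the low-to-mid 90s, idPhi around 0.01
rad/sample); group × setup contrasts are expressed as `agent_spec`
overrides per cell, not by re-tuning these defaults.

What the simulator does *not* emulate: head bobbing and gait dynamics,
speed modulation, fatigue or learning across blocks, landmark-specific
gaze, or any sensory noise model — agents are abstractions sufficient to
span the metrics' ranges with known ordering. Passing parameter-recovery
tests therefore shows that the *pipeline* recovers injected behavioral
differences; it does not certify the agent model as a model of human
navigators.

Every source of randomness derives from one master seed through a
polynomial hash (`derive_seed()`), with a fresh substream per trial —
mirroring the disorientation task's role of decorrelating consecutive
trials — so simulations and metric tables are bit-reproducible.

## Aggregation and export

Summaries follow the repeated-measures convention: trial values are
averaged within participant (per group × setup × trial type), then
summarized across participants as mean and `SEM = sd/√n`, with `n` the
participant count; a pooled-trials option exists. Probe trials are scored
against the block's *last* learning trajectory. `export_model_table()`
emits the one row per participant × setup × metric long table (with
session-order, sex, age and education covariates when available) for
downstream mixed-model fitting — the inference itself is deliberately out
of scope. The conventional log-transform rule for heavily non-normal
metrics (skewness outside ±2 or excess kurtosis outside ±7) is available
as an explicit flag and recorded per row.

## Numerical choices and degenerate inputs

* Wall containment is validated with a 1 mm tolerance; simulated agents are
  clipped strictly inside the wall.
* Rotation alignment is undefined for a trajectory starting at the exact
  center; this errors rather than guessing.
* A target on or outside the arena boundary is rejected (the reference
  distribution would be ill-defined).
* Grid binning covers `[−R, R]²` with `grid_n = 20`; boundary samples are
  clamped into the edge cells. Cell visitation is sample-based, which is
  exact at these sampling rates and speeds (≤ 1.4 m/s at ≥ 60 Hz cannot
  skip a 0.38 m cell).
* CSV output formats numbers at 17 significant digits, so sessions and
  metric tables round-trip to machine precision, and missing metrics are
  written as empty fields, never zero.

## Problem sizes used in the shipped tests

The validation suite runs cohorts of 2–9 participants (full 6-block × 7-
trial sessions in both setups), 50-seed paired agent comparisons, 1000-pair
DTW oracle sweeps at `m, n ≤ 7`, and a 5000-trial chance-level check; the
acceptance script scores 10,000 uniform responses at 1000 reference points
each. These sizes give comfortable statistical margins for every ordering
and tolerance asserted while keeping a full run in the order of a minute.

## Known limitations

* The loader reads the package's own CSV dialect (documented in
  `read_session()`); recordings in other layouts need column renaming and,
  if their ground-plane axes differ, the `axis_map` option.
* Surface coverage inherits the full-width bounding-box form, so values are
  not percentages of area actually visited; compare within, not across,
  conventions.
* idPhi in its default per-step unit is not comparable across different
  sampling rates — use `per_second = TRUE` for that.
* The memory score saturates at 0 once the response disk covers the arena;
  differences between very poor responses are not resolved.
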