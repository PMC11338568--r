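---
title: "Footstep synchronization and lane formation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Footstep synchronization and lane formation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crowdstep)
```

## The problem

When two groups of pedestrians walk toward each other along a corridor they
spontaneously segregate into unidirectional lanes. In single-file crowds,
pedestrians are also known to synchronize their footsteps with the person
ahead. `crowdstep` implements the full analysis chain needed to ask whether
footstep synchronization occurs in two-dimensional bidirectional flow, and
what an external auditory pacing cue (a 120 beats-per-minute metronome, the
CUE condition) does to the spatial self-organization relative to unpaced
walking (NO_CUE).

The pipeline covers: heel-strike extraction from shank-mounted inertial
sensors, a follower–predecessor pairing built on a lagged proximity
relation, in-phase/anti-phase classification of matched steps, a
pair-shuffling permutation null, lane clustering and counting, trial stage
segmentation, and a set of structural-instability metrics (time and distance
to potential collision, trajectory curvature, transverse mean squared
displacement, shoulder rotation), closed by Welch/Cohen/Pearson statistics.

## Coordinates, corridor, clocks

All positions are metres in a fixed frame: x runs along the corridor long
axis, increasing in the rightward group's travel direction, with the origin
at the measurement-area entrance used by that group; y is transverse and
must stay within `[0, 3]` m (`trial_dataset()` rejects fixtures whose axes
have been swapped). The measurement area is 10 m x 3 m, with a central
3 m x 3 m counting window, 1.2 m buffer zones and 8.4 m waiting areas at
both ends. All files of a trial share one clock starting at the trial start
signal; trajectories are sampled at 30 Hz, inertial traces at 100 Hz, and no
resampling is performed — every operation looks up nearest samples only.

## Step matching and synchronization

Pedestrian *i* follows *j* at time *t* when *i*'s position at *t* is within
`dr = 0.7` m of *j*'s position at `t - dt`, `dt = 1` s. For each
instrumented follower, the predecessor is the pedestrian followed for the
longest total time in the trial (ties toward the lower id). Each
predecessor strike between its first and last strike inside the measurement
area is matched to the nearest strike of the corresponding follower foot.

A match with follower/predecessor strike times `t_f`, `t_p` and single-foot
step durations `dt_f`, `dt_p` is *in-phase* when `|t_f - t_p| <= K`
(`K = 0.1` s), *anti-phase* when the offset is within `K` of plus/minus a
quarter of the summed durations, and either label additionally requires
duration conformity `|dt_f - dt_p| <= (dt_f + dt_p)/8`. The phase shift
reported in histograms is the offset normalized by the mean single-foot
duration, `wrap(2*pi*(t_f - t_p)/((dt_f + dt_p)/2))` in `(-pi, pi]`, so
in-phase steps map near 0 and anti-phase steps near plus/minus pi — the only
normalization consistent with a bimodal in-/anti-phase histogram.

Two genuinely open choices are settled as follows:

* **Foot correspondence** (`follow_params(foot_rule = )`). The default,
  `"same_side"`, pairs the predecessor's left foot with the follower's left
  foot (and right with right). The alternative, `"nearest_offset"`, picks
  for each predecessor foot the follower foot minimizing the mean absolute
  nearest-strike offset. The nearest-offset rule looks natural but has a
  strong selection artefact: it folds every offset into the inner
  half-cycle, so phase shifts concentrate in `(-pi/2, pi/2)`, anti-phase
  stepping becomes invisible, and the phase histogram of genuinely
  independent walkers is far from uniform. Side-correspondent pairing keeps
  the half-cycle structure (a follower striding on the opposite parity shows
  up at plus/minus pi) and leaves independent walkers uniform on the circle,
  which is the behaviour the analysis is designed to detect.
* **Step duration at a strike** is the backward difference to the previous
  same-foot strike; the first strike of a series takes its adjacent stride's
  duration. Matches are per predecessor strike; a follower strike may be
  reused by two predecessor strikes (dense crowds make this rare).

### The permutation null

The null asks how much synchronization two pedestrians show *by chance*.
For every pair in every trial of a condition the follower is kept and the
predecessor replaced by the predecessor of a uniformly chosen pair from a
uniformly chosen *other* trial of the same condition, excluding pairs
containing either member of the original pair. Strike series are compared on
the shared trial-start clock, so a condition paced by a common external
metronome remains synchronized under shuffling (the clock is global), while
spontaneous coordination does not survive it. One master seed draws
per-shuffle substreams, making the ensemble reproducible and independent of
evaluation order. Statistical comparisons treat the 1000 shuffle summaries
as one sample of size 1000.

When a chi-square uniformity check is applied to phase shifts, it is applied
to **one value per pair** (the circular mean of the pair's phase shifts),
not per match: a pair holds a slowly drifting relative phase, so its matches
are strongly dependent and would invalidate the test's sampling model.

## Lanes and stages

Lanes at time *t* are the connected components of the undirected closure of
the following relation over pedestrians currently inside the measurement
area (union–find, same-group edges only by default: lanes are
unidirectional, and a head-on "following" at closing speed is physically
spurious). The lane count of a trial averages, over all sample times in
stages 2–4, the number of components with at least one member inside the
central window.

The six stage instants are: first entry (t0), first crossing of the two
groups' front-most pedestrians (t1), first exit (t2), last entry (t3), last
crossing of any cross-group pair (t4), last exit (t5). Crossings are
detected as sign changes of the x-gap on the 30 Hz grid. When the first
exit precedes the last entry fails to hold in the usual order — i.e.
`t2 > t3` — the full-bidirectional-flow stage (stage 3) is undefined and
four stage intervals are returned; overlapping stage intervals contribute
each sample time once to stage averages.

## Instability metrics

* **Time to potential collision**: each cross-group pair is linearly
  extrapolated at current velocities (backward difference over 1 s — the
  same differencing rule as curvature, so the two metrics cannot disagree
  about what "current velocity" means); tau is the smallest value of the
  grid `{0.03, 0.06, ..., 9.0}` s at which the extrapolated distance drops
  to `delta_c = 0.6` m, found in closed form from the quadratic distance
  function and then snapped up to the grid, so every reported tau is an
  exact grid element. Distance to collision is
  `lambda = tau (|v_i| + |v_j|)/2`. Trial means average all finite
  pair-time records; pairs with no qualifying grid value contribute nothing
  (padding them with 9 s would bias the mean), and a per-pedestrian-minimum
  mode is available for sensitivity analysis.
* **Curvature** `kappa(t) = |e(t+dt) - e(t)|/dt` with `e` the unit velocity
  vector and `dt = 1` s, evaluated on a 1 s grid; zero-velocity samples are
  skipped. `kappa` is bounded by `2/dt` and invariant under rigid motions.
* **Transverse MSD** `D(t) = <(y(t) - y(0))^2>` with each pedestrian's
  clock zeroed at measurement-area entry, reported up to the shortest
  in-area duration so all pedestrians contribute to every lag.
* **Shoulder rotation**: the angle between the shoulder segment and the
  y-axis, folded into `[0, pi/2]`, averaged per pedestrian and then per
  trial.

## The synthetic generator

No public dataset accompanies the experiment, so the package ships a seeded
kinematic generator that reproduces its statistical structure with known
ground truth; it is first-class, tested code, not a fixture.

Two groups of 24 pedestrians start on opposing 8 x 3 grids of start lines
1.2 m apart and walk toward opposite corridor ends. Lanes are the generator's
ground truth rather than an emergent property: `n_lanes` unidirectional
lanes alternate travel direction across the width, each pedestrian is
assigned round-robin to its group's lanes, and its y relaxes exponentially
(time constant 0.5 s) toward the lane centre under mean-reverting
Ornstein–Uhlenbeck noise, plus a transverse deflection away from any
oncoming pedestrian within 2 m ahead at lateral offset below 0.5 m, with
reflective clamping at the walls. Walking speed is drawn once per lane from
`N(1.3, 0.1)` m/s — a platoon moving at common speed. This is deliberate:
with independent per-pedestrian speeds, within-lane spacing drifts through
the 0.7 m following window over a 15 s trial and lanes dissolve, destroying
the ground truth that the clustering recovery tests rely on. The speed
values themselves are conventional walking speeds, configurable, and not a
claim about any particular dataset.

Gait is an alternating-foot phase model at tempo 120 strikes/min combined
(per-foot stride frequency 1 Hz, feet half a cycle apart). In
`metronome_locked` mode strikes sit on the metronome ticks (tick train from
t = 0; each pedestrian starts on a random foot) plus `N(0, 0.02^2)` s
jitter; in `independent` mode each pedestrian draws a stride frequency
`N(1, 0.05^2)` Hz — consistent with unpaced cadence staying within a few
percent of 120/min — and a uniform initial phase. `duration_coupling` pulls
each pedestrian's frequency toward its within-lane predecessor's by the
given fraction, front to back, emulating the spontaneous duration
coordination of unpaced crowds (defaults: 0.5 in the NO_CUE preset; at 1.0
a lane is frequency-locked, a useful limit check).

The two condition presets differ in gait mode and in space:
`condition_preset("CUE")` uses the metronome, one more lane (4 vs 3) and
half the lateral noise (0.05 vs 0.10 m) of `condition_preset("NO_CUE")` —
the spatial signature of paced crowds (thinner lanes, less lateral
exploration) is imposed, not emergent, because the generator is kinematic.
Synthetic IMU traces place a unit Gaussian bump (60 ms FWHM) at each heel
strike and a negative bump at each toe-off (60% into the stride), plus
white noise, which closes the loop with the detector at its stated +/-10 ms
accuracy.

Shoulder markers model the trunk, not the instantaneous velocity: the
shoulder axis sits on the y-axis (pedestrians face their travel direction
despite lateral sway), acquires a 0.35 rad yaw — relaxation time 0.3 s —
whenever an oncoming pedestrian passes within 2 m ahead at a lateral offset
below the combined shoulder clearance (0.8 m: two 0.4 m shoulder widths),
and carries 0.03 rad postural jitter. Rotation therefore increases with the
frequency of close passes, i.e. with thinner lanes; this is the mechanism
the rotation metric is meant to capture. The avoidance *deflection* keeps
its own, tighter 0.5 m trigger: pedestrians yield lateral space only when a
collision is actually imminent but turn their shoulders already at passing
distance.

What the generator does **not** emulate: force-based interactions, density
dependence, overtaking, body contact, demographic heterogeneity, and any
feedback from gait onto trajectory. Consequently, passing tests demonstrate
that the pipeline recovers known structure under controlled conditions —
not that real crowds behave like the generator; condition differences in
the synthetic experiment are by construction and validate directions and
machinery, never effect sizes of real data.

## Heel-strike detection

The detector median-filters the medio-lateral angular velocity (window 5
samples), takes strict local maxima (plateaus resolve to their leftmost
sample), keeps those reaching at least 30% of the filtered trace maximum,
enforces a 0.4 s minimum separation greedily by height (earlier peak on
ties), and, when toe-off/heel-strike interval annotations are present,
restricts candidates to those swing intervals. This is a self-contained
surrogate for IMU gait-event detection: the downstream analyses only need
strike times to about 10 ms, which the closed loop with the synthesizer
verifies. The separation and prominence thresholds are engineering
defaults exposed in `detection_params()`; the window length of 5 is the
analysis convention for this sensor setup.

## Numerical conventions

* Nearest-sample lookup everywhere (30 Hz grid; the worst-case 17 ms
  position error is negligible against `dr = 0.7` m); no interpolation.
* Ties: follow-duration ties to the lower pedestrian id; equidistant
  strikes to the earlier one; plateau maxima to the leftmost sample.
* Degenerate inputs return sentinels or typed errors: a track never
  entering the measurement area yields `NA` entry/exit; zero matches yield
  an `NA` synchronization summary; an all-constant IMU trace yields an
  empty series with a warning.
* Angles wrap into `(-pi, pi]`; shoulder angles fold into `[0, pi/2]`.

## Problem sizes

The test suite exercises full-size trials (2 x 24 pedestrians) where the
property under test concerns crowd structure, and 2 x 6-pedestrian trials
for invariance and plumbing checks. Chance-level recovery uses six
independent-phase trials against a 10^6-draw Monte-Carlo oracle and a
1000-shuffle null; the duration-coupling direction check uses twenty
two-trial replicates; the collision-risk ordering check uses ten paired
replicates. `scripts/acceptance.R` replicates the full design — 20 trials
per condition, 1000 shuffles per null — in a few minutes on one CPU.

## Known limitations

* The generator's lane count is imposed; it cannot test lane *emergence*.
* Shoulder rotation in the generator responds only to avoidance episodes;
  its condition-level direction depends on preset geometry and is not a
  validated prediction.
* The stage segmentation assumes both groups traverse the area once;
  re-entries would extend stage 5.
* `welch_compare()` refuses two zero-variance samples with different means
  (infinite t); Cohen's d is `NA` when both variances vanish.
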