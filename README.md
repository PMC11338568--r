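# crowdstep

Footstep synchronization and spatial self-organization in bidirectional
pedestrian flows.

When two groups of pedestrians walk toward each other along a corridor they
self-organize into unidirectional lanes. In single-file crowds pedestrians
are also known to fall into step with the person ahead — but does footstep
synchronization occur when walkers are free to move in two dimensions, and
what does pacing a crowd with an external metronome (120 beats min⁻¹; the
CUE condition, vs. unpaced NO_CUE) do to the robustness of the lanes it
forms? `crowdstep` implements the complete analysis pipeline for this kind
of experiment, together with a seeded synthetic generator of
bidirectional-flow trials with known ground truth, so every stage is
testable without any experimental data.

## What the package computes

For trials of two groups (24 pedestrians each) crossing a 10 m × 3 m
measurement corridor, tracked at 30 Hz with 100 Hz shank IMUs:

* **Heel strikes** from medio-lateral angular velocity: median filter
  (window 5), prominence-constrained peak picking, optional toe-off gating
  (`detect_heel_strikes()`).
* **Pairs**: pedestrian *i* follows *j* at *t* if |**r**ᵢ(t) − **r**ⱼ(t −
  dt)| < dr, with dt = 1 s, dr = 0.7 m; the predecessor of a follower is
  the pedestrian it followed longest (`identify_pairs()`).
* **Synchronization**: a matched step is in-phase if |t_f − t_p| ≤ K
  (K = 0.1 s), anti-phase if |t_f − t_p ∓ (Δt_f + Δt_p)/4| ≤ K, requiring
  duration conformity |Δt_f − Δt_p| ≤ (Δt_f + Δt_p)/8; per-trial
  proportion synchronized, phase-shift histograms, duration differences
  (`classify_step()`, `trial_sync_summary()`).
* **Permutation null**: 1000 virtual trials re-pairing each follower with a
  predecessor from another trial of the same condition
  (`shuffle_null()`), plus the kth-nearest-neighbour strike discrepancy
  δₖ(t) (`neighbour_discrepancy()`).
* **Lanes and stages**: lanes as connected components of the following
  relation, counted in the central 3 m × 3 m window and averaged over
  stages 2–4 of the six-instant stage segmentation t₀…t₅
  (`lane_partition()`, `mean_lane_count()`, `stage_boundaries()`).
* **Structural instability**: time to potential collision τ(t) = min{τₙ ∈
  {0.03, …, 9.0} s : |**f**ᵢ(t,τₙ) − **f**ⱼ(t,τₙ)| ≤ 0.6 m} under linear
  extrapolation, distance λ = τ(|vᵢ| + |vⱼ|)/2; trajectory curvature
  κ(t) = |(**e**(t+dt) − **e**(t))/dt|; transverse MSD D(t) = ⟨(y(t) −
  y(0))²⟩; shoulder rotation from marker positions
  (`trial_risk_means()`, `curvature()`, `transverse_msd()`,
  `shoulder_rotation()`).
* **Statistics**: Welch's t-test with Cohen's d, Pearson order trends, and
  a machine-readable condition-level report (`welch_compare()`,
  `order_trend()`, `build_report()`).

The generator (`simulate_trial()`, `condition_preset()`) produces seeded,
bitwise-reproducible trials with configurable lane structure,
Ornstein–Uhlenbeck lateral noise, metronome-locked or independent gait
phases, and duration coupling along lanes — with the ground truth returned
alongside the data.

## Worked example

```r
library(crowdstep)

sim <- simulate_trial(condition_preset("CUE", seed = 42))
sim$dataset
#> trial T01 (CUE): 48 pedestrians (24 rightward, 24 leftward), 48 step series

summ <- trial_summary(sim$dataset, delta_k = FALSE)
summ
#> trial T01 (CUE): prop_sync = 1.000, lanes = 3.97, tau = 1.78 s, lambda = 2.37 m

summ$stages
#> stage instants (s):
#>     t0     t1     t2     t3     t4     t5
#>  0.867  4.533  7.767  7.933 11.633 15.933

summ$pairs[[1]]
#> pair R04 -> R02: followed 16.77 s, 15 matched strikes

summ$sync
#> sync summary [T01]: prop_sync = 1.000, mean duration diff = 0.0299 s, 302 matches
```

The trial is metronome-locked, so every matched step is synchronized
(`prop_sync = 1.000`) and the mean duration difference between paired
walkers (0.03 s) is pure timing jitter. The CUE preset forms four lanes;
the recovered mean lane count is 3.97. The first pedestrian enters the
measurement area at t₀ = 0.87 s, the group fronts cross at t₁ = 4.53 s,
and the last pedestrian leaves at t₅ = 15.93 s. Mean time and distance to
potential collision (1.78 s, 2.37 m) quantify how exposed the organization
is to perturbations. On an unpaced trial
(`condition_preset("NO_CUE", seed = 42)`) the same pipeline yields
`prop_sync` near the chance level ≈ 0.39 and about three (wider) lanes.

A thin CLI covering simulation, step detection, per-trial analysis and the
null ensemble is installed at `inst/cli/crowdstep`.

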