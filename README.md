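# trackmorph

Dual-reference-frame place-field analysis on morphing linear tracks.

## The problem

Hippocampal place cells fire in restricted regions of an environment,
but a rigid environment cannot tell whether those regions are defined
in room-fixed (planar, 2D) coordinates or in track-centric (linear, 1D)
coordinates: the two descriptions coincide. A morphing track breaks the
degeneracy. When the track's geometry changes while its connectivity is
preserved, a room-anchored field keeps its planar position and drifts
along the track, whereas a field anchored to the sequence of places
along the track keeps its linearized position `x_l` and drifts through
the room.

`trackmorph` is for electrophysiologists and modellers who want to run
— or probe — this dissociation. It implements:

* parametric geometry for an **accordion U-track** (10 rigid segments,
  arms folding under the equal-angle constraint
  `∠(1,2) = ∠(3,4) = α`) and a **protrusion-flip track** (11 segments,
  a three-segment detour flipping between the two sides);
* **occupancy-normalized rate maps** on a 3 cm grid in both frames,
  averaged over random half-bin grid shifts, with a 3 cm/s speed
  filter and no other smoothing;
* the **configuration-correlation analysis**: configurations pooled by
  9 cm vertical sections (`N_V ≥ 3`), per-cell correlation matrices
  `C_ij` over section pairs in each frame, subdiagonal decay curves
  `r_d = ⟨C_{i,i+d}⟩`, mobile/static cell splits, and per-`d` Welch
  tests between frames;
* the **protrusion battery**: Flip, Distance, Segment and Rescaled
  correlations across a protrusion-flip session pair, with
  Mann–Whitney u-tests and one-way ANOVA + Tukey–Kramer statistics;
* a **synthetic-data module**: alternation trajectories (~34 s runs,
  pseudo-random arm moves executed while the agent pauses at the
  opposite well) and inhomogeneous Poisson spike trains from Gaussian
  fields anchored under selectable hypotheses — `planar`,
  `linear_fraction` (elastic track coordinate), `segment_bound`,
  `distance_from_well`.

See `vignettes/morphing-track-analysis.Rmd` for the models, parameter
choices and numerical details.

## Worked example

Simulate a session at the study conditions — 50 cells with elastic
(sequence-anchored) fields, 40 track moves — and run the full Track A
analysis:

```r
library(trackmorph)

bundle <- simulate_session(n_moves = 40, n_cells = 50,
                           anchoring = "linear_fraction", seed = 1)
result <- run_track_a(bundle)
print(result)
#> Accordion-track dual-frame analysis
#>   cells: 26 mobile, 24 static, 0 unclassified
#>   mobile ensemble r_10: linear 0.638, planar -0.129 (gap 0.767)
#>   frame pattern: linear-stable (fields track the linearized frame)
```

`r_10` is the mean correlation between rate maps of configurations ten
vertical sections apart (~90 cm of arm travel): for sequence-anchored
cells the linearized maps stay correlated (~0.64) while the planar maps
decorrelate entirely — the fields move with the track, not the room.
Simulating with `anchoring = "planar"` reverses the pattern.

The protrusion-flip battery on the second track:

```r
pair <- simulate_protrusion_pair(n_cells = 100,
                                 anchoring = "linear_fraction", seed = 1)
res_b <- run_track_b(pair)
print(res_b$stats)
#> Protrusion-flip comparison battery
#>   flip      mean r = -0.083 (SEM 0.024, n = 100)
#>   distance  mean r = -0.132 (SEM 0.026, n = 100)
#>   segment   mean r = +0.198 (SEM 0.039, n = 98)
#>   rescaled  mean r = +0.363 (SEM 0.033, n = 100)
#>   highest: rescaled; one-way ANOVA p = 8.62e-31
res_b$hypothesis
#> [1] "linear_fraction"
```

Fields neither follow the flipped segments (flip ≈ 0) nor stay at fixed
well distances (distance ≈ 0); rescaling the protrusion span onto the
section that replaces it recovers the strongest correlation — the
fields stretch and shrink with the local deformation.

Sessions round-trip through plain text tables with
`write_session()` / `read_session()`.

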