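---
title: "Dual-frame place-field analysis on morphing tracks: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-frame place-field analysis on morphing tracks: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trackmorph)
```

## The scientific question

A hippocampal place cell fires when the animal occupies a restricted
region of its environment. Whether that region is defined in *room*
coordinates (an allocentric, metric map) or in *track* coordinates (a
sequence-preserving, topological map) cannot be decided on a rigid
environment, because the two descriptions coincide. A morphing track
breaks the tie: when the geometry of the track changes while its
connectivity does not, a field anchored to the room stays put in planar
coordinates and wanders along the track, while a field anchored to the
sequence of places stays put in linearized coordinates and wanders
through the room.

`trackmorph` implements the complete analysis for two such apparatus
designs, together with a synthetic generator that produces behaviour and
spike trains under *known* anchoring hypotheses, so the discriminating
power of every statistic can be verified on ground truth.

## Track models

**Accordion U-track (Track A).** Ten rigid 40 cm segments form a U:
segments 1–4 (top arm) and 7–10 (bottom arm) fold accordion-style at
their joints; segments 5–6 are the static base. All joint angles on an
arm are equal (`∠(1,2) = ∠(3,4) = α` on the top arm, `β` on the bottom),
so one number — the horizontal extent of the arm's food well — fixes the
arm's pose. We model the fold with alternating signs, segment *k*
pointing at `±θ` to the horizontal with `α = 180° − 2θ`; the well then
sits at `4·L·cos θ` from the base, and the 140 cm travel span fixes the
minimum extent at 20 cm. Joints are modelled as zero-length connectors:
the total linearized length is then exactly 4 m, matching the physical
track, and no arbitrary arc length needs to be invented for the joint
circles.

Arm poses are summarized by **vertical sections**: twelve 9 cm columns
indexed 1 (most contracted) to 12 (most extended). Twelve 9 cm sections
cover 108 cm of the 140 cm physical sweep; we anchor the grid at the
contracted end, clamp indices into 1–12, and let the default extent
sampler draw inside the section-covered range, so every simulated
configuration falls in a proper section. The geometric dissimilarity of
two configurations is the difference `d` of their section indices.

**Protrusion-flip track (Track B).** Eleven segments; three of them form
a mobile trio that protrudes as a rectangular detour (out, across, back)
on one side of the U, and flips to the matching slot on the other side
between sessions. The vacated slot is spanned by a single in-line
segment, so each configuration deploys a 360 cm path, identical for the
two sides; positional labels 3,4,5 and 7,8,9 denote the same three
physical segments before and after the flip, with path order preserved
so the centre (across) segment stays central and projects straight onto
the in-line section that replaces the detour. The detour therefore
inserts 80 cm of extra path locally without changing the track's
topology.

## Reference frames and rate maps

Positions live in two frames: planar room coordinates `(x, y)` and
linear track coordinates `(x_l, y_l)` — arc length from well F1 along
the midline and signed lateral offset. Both are binned into 3 cm bins,
and rates are occupancy-normalized: seconds of occupancy and spike
counts are accumulated per bin and divided. Because the absolute
placement of the grid is arbitrary, each map is the average of 25 maps
computed on grids shifted by uniform random offsets up to half a bin in
each axis, a form of unbiased de-pixelation; no other smoothing is
applied. Grids carry one *guard bin* on every edge so that samples near
the boundary are never lost under a shifted registration — spike-count
and occupancy conservation hold exactly for every shift.

Two numerical details matter in the sparse-pass regime:

* **Interval durations are attached to samples** (`dt_s`) before any
  subsetting, so pooling epochs or restricting to a region never
  manufactures spurious long intervals across gaps.
* **Peak rates use an occupancy floor** (0.2 s by default): a bin grazed
  for a single 40 ms sample yields rate estimates of 25–50 Hz from one
  or two spikes, which would otherwise dominate every peak statistic.
  The floor is an estimator choice only; it does not affect occupancy,
  counts, or the correlation masks. Field *centres* are estimated from
  the laterally-marginalized rate profile, since the centre is a
  one-dimensional quantity and the three lateral bins only add noise.

Samples (and their spikes) taken below 3 cm/s are excluded throughout;
speed is the central difference of box-smoothed (5-sample) positions.

## The configuration-correlation analysis (Track A)

Because single passes yield few spikes, configurations are pooled by
vertical section, and only sections populated by at least `N_V = 3`
configurations enter the analysis. For every cell and frame we build one
pooled rate map per section (occupancy and counts pooled *before*
normalization) and correlate all section pairs, giving a 12 × 12 matrix
`C_ij` per frame. A bin enters a pairwise correlation only if it was
visited in both maps and at least one spike was fired there; the
published phrasing is ambiguous between "a spike in either map" and "a
spike in both", so both rules are implemented (`mask_rule`), with
"either" as the default — the stricter rule discards nearly empty
vectors and inflates correlations among the surviving bins. Entries with
fewer than 10 valid bins or zero variance are undefined and excluded,
never imputed. Grid shifts are shared between the two maps of a pair
(drawn once per frame per analysis), which removes shift-sampling
variance from the comparison.

The subdiagonal mean `r_d = ⟨C_{i,i+d}⟩` traces how similarity decays
with geometric dissimilarity. Cells are classified mobile or static by
whether their linear field peak falls in the arc span of base segments
5–6 (half-open `[160, 240)` cm); mobile cells are analysed on their own
arm's sections and region, static cells on the base region. Ensembles
average the per-cell matrices element-wise, and the two frames are
compared at each `d` with Welch two-sample t-tests across the per-cell
subdiagonal values (the dispersion shown with curves is likewise the
across-cell SEM — the across-entry alternative is available from the
per-cell matrices).

Directions of travel are pooled: on this apparatus fields did not depend
on running direction, and halving the passes per map would be costly in
the 3–7-pass regime.

## The protrusion battery (Track B)

All four comparisons are computed on linearized data, for every cell
whose peak rate exceeds 2 Hz in at least one session:

* **Flip** — protrusion span vs. the same physical segments after the
  flip, aligned by material position (tests feature-bound fields).
* **Distance** — protrusion span vs. the bins at the same arc distance
  from the corresponding well in the other session (tests pure distance
  coding). With equal path lengths on both sides this is the
  same-`x_l` window.
* **Segment** — the protruding centre segment vs. the in-line section it
  projects onto after the flip, aligned proportionally.
* **Rescaled** — the whole protrusion span linearly compressed onto the
  replacing in-line section (spikes and occupancy transformed together,
  so both are conserved exactly), vs. that section's rates (tests
  elastic stretching).

Spans of unequal physical length are laid on common grids of
`round(length/3)` equal bins; rates are re-binned by coordinate
transformation with no interpolation. Each comparison is evaluated in
both directions (session 1's protrusion and session 2's) and averaged
per cell over the defined directions. Group statistics use Mann–Whitney
u-tests for all pairs, and a one-way ANOVA with Tukey–Kramer post-hoc
contrasts across the four groups; the comparison with the highest mean
identifies the supported hypothesis (rescaled/segment → elastic
fraction, flip → segment-bound, distance → distance-from-well).

## The synthetic generator

The generator reproduces the statistical structure the analysis assumes,
not the biophysics of CA1.

**Schedule.** Each track move draws new extents for both arms
independently (the two arms' motions are unrelated in sign, as on the
physical apparatus); the default is 40 moves per session, within the
10–80 range of the emulated protocol. Because 41 configurations spread
over 12 sections leave each section barely 3.4 visits in expectation, an
iid sampler fails the `N_V ≥ 3` requirement in almost every draw; the
default sampler is therefore stratified — at least three extents per
section, uniform within the section, in shuffled order — with an iid
option that retries a bounded number of times and flags failure.

**Behaviour.** The agent alternates F1 → F2 → F1…, pausing ~10 s at the
well while the track assumes the next configuration (moves happen only
while the animal is at a well, as in the protocol), then runs along the
new midline with a smooth autoregressive speed profile around
400/34 ≈ 11.8 cm/s — so a full run takes ~34 s — and bounded lateral
wander (AR(1), 1.2 cm s.d.) within the 8 cm runway. Positions are
sampled at 25 Hz.

**Cells.** Each cell has a single Gaussian field:
`rate = baseline + (peak − baseline)·exp(−Δ²/2σ²)` with peak 15 Hz,
baseline 0.1 Hz, σ = 10 cm by default — no widths or rates are published
for the recorded cells, so these are conventional values for CA1
pyramidal fields that yield a handful of spikes per pass. `Δ` is the
distance to the field centre *in the cell's anchored coordinate*, which
is the experimental variable:

* `planar` — Euclidean distance to a fixed room point;
* `linear_fraction` — distance along the *canonical* (elastic) track
  coordinate;
* `segment_bound` — distance to a material point on a physical segment,
  wherever that segment lies;
* `distance_from_well` — difference in arc distance from a food well.

On Track A the canonical coordinate is simply `x_l` (the deployed path
never changes length, so a fixed fraction of the track is a fixed
material point). On Track B the two protrusion slots are elastic: the
canonical axis gives each slot one segment length, and mapping through
it stretches a field threefold when the detour is deployed — the
sequence-preserving prediction that fields stretch and shrink with the
local deformation. A literal whole-track fraction would be inert here,
because both configurations have the *same* total path length; the
elastic coordinate is the definition under which "fraction of the
track" has the intended topological meaning, and it is what the
`linear_fraction` label denotes throughout this package. An optional
per-configuration gain implements rate remapping (amplitude changes
with the anchored centre fixed).

**Spikes.** Inhomogeneous Poisson: the rate is held constant over each
40 ms sample, counts are Poisson with mean `rate·dt`, and spike times
are uniform within the interval — the exact distribution a thinning
sampler converges to for a piecewise-constant intensity. One master
seed drives schedule, trajectory, cells and spikes through fixed
sub-streams, so every artefact is reproducible end-to-end.

What the generator deliberately omits: theta modulation and phase
precession, burstiness and refractoriness, multi-field and interneuron
activity, global remapping, overdispersion beyond Poisson, and any
head-direction or speed dependence of rate. Passing tests therefore
show that the *analysis* separates the coding hypotheses under the
protocol's sampling constraints — not that real CA1 data are this
clean.

## Problem sizes and what the checks compute

The package's own verification uses 50-cell, 40-move accordion sessions
(five seeds per anchoring, matrices pooled across sessions as for
combined animals), 100-cell protrusion pairs of two 20-minute sessions,
and twenty seeded replicates of the hypothesis-identification loop.
At these sizes the full chain reproduces: stable linear-frame
correlations with decaying planar-frame correlations for elastic cells
(ensemble gap > 0.3 at `d = 10`, Welch p < 0.01 from mid-range `d`),
the reversed pattern for planar-anchored cells, no frame divergence for
static-base cells, the rescaled > segment > flip/distance ordering of
the protrusion battery with flip near zero, and > 90 % of elastic field
centres recovered within 1.5 bins.

## Known limitations

* The exact contracted zigzag shape at the inner joints is not
  published; the alternating-sign fold is the simplest pose satisfying
  the equal-angle constraint and the printed travel span. Linearization
  near tight folds is genuinely ambiguous for points equidistant from
  two legs — the forward (planar → linear → planar) mapping is exact,
  but real tracking noise at contracted poses would need care.
* The published bottom-arm section grid is "slightly displaced" by an
  unstated amount; we use no offset.
* Track B's in-line replacing section is modelled as furniture (no cell
  anchors to it), and the trio's material orientation is assumed
  preserved in path order across the flip.
* Correlations between far-apart planar configurations rest on few
  valid bins (the configurations barely overlap in the room); entries
  below the 10-bin floor are undefined and simply excluded, which is
  also how sparsely sampled real sessions behave.
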