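---
title: "Mapping retinal orientation selectivity: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping retinal orientation selectivity: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(osmapr)
```

This vignette explains the models and procedures behind `osmapr`, the
assumptions they make, the parameters that matter, and the design choices
taken where several reasonable options existed. It states no empirical
result beyond what the package's own tests and `scripts/acceptance.R`
compute.

## The scientific problem

Some retinal neurons (ganglion and amacrine cells) are orientation
selective (OS): they respond most strongly to an elongated stimulus moving
along one axis and weakly to the orthogonal axis. In large-scale
two-photon calcium imaging of the ganglion cell layer, each field of view
(FOV) yields hundreds of cells' dF/F responses to a moving-bar protocol
(k directions x R repetitions). `osmapr` covers the full analysis chain
for such data:

1. per-cell tuning summaries (quality index, vector-sum tuning, DSI/OSI,
   preferred angles);
2. statistical selectivity calls by a block-shuffled permutation test;
3. functional subtype discovery by k-means + silhouette analysis;
4. map-level statistics of how preferred orientation varies with retinal
   location;
5. a concentric circle/ellipse model of the orientation map, with
   anchor/aspect fitting by area-between-quadratic-fits minimization.

A synthetic-retina generator produces ground-truth data with the
statistical structure the analysis assumes, so every stage is testable
without imaging data.

## Coordinate and angle conventions

All geometry uses one fixed frame: origin at the optic nerve, +x temporal,
+y dorsal, angles counterclockwise from +x. Orientation axes live in
[0, 180) degrees and are normalized there at every I/O boundary; motion
directions live in [0, 360). The ventral cardinal axis is the vertical
(90-270 degree) axis. The ventronasal (VN) and ventrotemporal (VT)
sampling axes run at 225 and 315 degrees through the optic nerve.

The signed *deviation from ventral* of an axis `phi` is `90 - phi`, in
(-90, 90]: negative for VN-leaning axes, positive for VT-leaning ones, +90
for the horizontal axis (a convention at the boundary). Under this sign
choice, concentric circles anchored at the optic nerve predict a constant
-45 degrees along the VN axis and +45 along VT. Preferred orientation is
reported in motion-axis space (half the double-angle phase); a bar's long
axis is orthogonal to its motion axis, so comparisons with bar-axis
conventions must rotate by 90 degrees.

## Per-cell tuning

**Quality index.** `quality_index()` computes the variance over time of
the across-repetition mean trace divided by the mean across repetitions of
the per-repetition time variance. It equals 1 when all repetitions are
identical and approaches 1/R for pure i.i.d. noise. Cells pass the quality
filter only if QI strictly exceeds 0.6 (the conventional threshold for
this index; a cell at exactly 0.6 is dropped). When all traces are flat
the denominator vanishes; QI is then defined as 0 with a `degenerate`
flag rather than an error, so batch pipelines proceed.

**Peaks.** "Average peak response" is read as the mean over repetitions of
each repetition's maximum inside the response window, not the peak of the
mean trace: the phrase orders "average" outside "peak", and per-trial
maxima are robust to trial-to-trial timing jitter. The response window is
the union of the stimulus-on and post-offset windows (so OFF responses
count); the exact window is a protocol parameter because reasonable
choices differ.

**Selectivity statistics.** `L_dir` is the modulus of the
response-weighted sum of unit vectors at the stimulus directions, divided
by the summed responses; `L_ori` is the same in double-angle space, where
opposite directions reinforce instead of cancel. Half the phase of the
double-angle sum is the preferred orientation. DSI contrasts the sampled
direction nearest the vector-sum direction against its opposite; OSI
contrasts the largest of the four orientation-averaged responses against
its orthogonal. The OSI "pref" (an argmax) and the vector-sum phase can
disagree; both are stored. Because DSI's "pref" is tied to the vector sum
rather than the argmax, DSI can be slightly negative for weakly tuned
cells. All angle arithmetic uses the two-argument arctangent on summed
cosines and sines — no slopes, no infinities.

A cell responding to exactly one direction has `L_dir = L_ori = 1`; this
degeneracy is why selectivity is decided by testing both statistics
jointly rather than by thresholding either one.

## Permutation significance

Tuning statistics have no convenient finite-sample null, so significance
is decided by permutation: the direction labels of whole trials are
shuffled (a *block* is one trial's full trace, preserving within-trial
autocorrelation), peaks and the statistic are recomputed, and the cell is
called selective iff its observed `L_dir` or `L_ori` strictly exceeds more
than 95% of 1000 permuted values. Ties count against significance, which
is conservative for degenerate cells (e.g. all-constant responses have
observed = permuted = 0 and are never called). Per-trial maxima are
invariant under relabeling, so they are computed once and only
re-aggregated per permutation, making 1000 permutations cheap. Each cell
uses an RNG substream derived from (global seed, cell index), so results
do not depend on evaluation order. Under the null the exact false-positive
rate is 50/1001 (the observed value must rank in the top 50 of 1001
exchangeable values), which the test suite verifies on 2000 simulated
non-selective cells. Cells significant for both statistics are classified
"both" and included in OS analyses (the overlap is well under 1% at
default settings).

## Subtype discovery

ON-OFF response features are the repetition- and direction-averaged trace,
cropped to the stimulus-on + post-offset windows, linearly resampled to 40
samples and peak-normalized — a shape-only descriptor. The feature
definition is deliberately transparent (no PCA, no scalar indices) since
the original analysis does not pin one down; window boundaries live in the
protocol.

k-means (best of 10 restarts per k) is run for k = 2..10 and each solution
is scored by the mean silhouette value, `SV(i) = (b(i) - a(i)) /
max(a(i), b(i))` with Euclidean distances (the metric k-means itself
optimizes); cohesion `a` is the mean distance to own-cluster members,
separation `b` the smallest mean distance to another cluster. Singleton
clusters get SV = 0, the standard convention. The chosen k maximizes mean
SV. A permuted-data control — features shuffled across cells independently
per dimension — reports the mean-SV curve of structureless data with the
same marginals. Clusters are named ONs / ONt / OFF by template rules on
their centroids: peak in the post-offset segment means OFF; otherwise the
sustainedness of the late stimulus-on segment (>= 0.5 of peak) separates
ONs from ONt; a centroid with no positive peak is labeled `unassigned`
rather than silently misnamed.

Preferred orientations are clustered as double-angle unit vectors
`(cos 2phi, sin 2phi)` so 0 and 180 coincide; the larger cluster is the
locally overrepresented orientation group and cluster separation is
measured as an axis angle.

## The synthetic retina

The generator emulates the structure of the imaging studies this analysis
targets, with defaults fixed at the study conditions:

| parameter | default | meaning |
|---|---|---|
| `fov_size_um` | 425 | FOV side (um) |
| `cells_per_fov_mean/sd` | 590 / 170 | segmented cells per FOV |
| `frac_os / frac_ds / frac_both` | 0.30 / 0.12 / 0.005 | selectivity classes |
| `subtype_mix` | 70/20/10% | ONs/ONt/OFF among OS cells |
| `subtype_tuning_kappa` | 1.5 / 2.5 / 4 | double-angle von Mises concentration, ONs/ONt/OFF |
| `underrep_frac` | 0.15 | orthogonal minority group |
| `map_anchor_xy_um` | (-100, -250) | concentric-map anchor |
| `map_aspect_ratio` | 1.09 | horizontal/vertical radius ratio |
| `angular_noise_kappa` | 10 | double-angle von Mises orientation noise |
| `n_directions x n_reps` | 8 x 5 | protocol |
| `frames_per_trial @ frame_rate` | 48 @ 10 Hz | trial timeline |
| `noise_sd` | 0.08 | i.i.d. dF/F noise |

OS cells' ground-truth orientations are the tangent angles of the
concentric-ellipse family through each cell's location (rotated 90 degrees
for the underrepresented group) plus von Mises noise applied in
double-angle space, the standard treatment of axial noise. Responses are
kinetic templates — piecewise double-exponentials with documented time
constants (ONs: 0.15 s rise, sustained with 6 s decay during the bar,
0.8 s decay after offset; ONt: 0.1 s rise, 0.4 s transient decay; OFF:
silent until offset, then 0.1 s rise / 0.4 s decay) — scaled by a von
Mises tuning gain (double-angle for OS, single-angle for DS, flat for
non-selective; product of both for "both" cells) plus Gaussian noise.
Tuning concentration is ordered inversely to prevalence (OFF most tuned,
ONs least), and the prevalence/tuning inversion propagates through the
measured `L_ori` (verified in tests at low noise; at default noise the
peak-extraction noise floor compresses the contrast between the sharply
tuned tails).

Values the source studies do not report — repetition count, trial timing,
tuning concentrations, angular-noise level, anchor coordinates, FOV sector
geometry (sector half-width 18 degrees, center distances 400-1400 um) —
were fixed once at what a retinal physiologist would call realistic and
are configurable. The anchor default is *shallow* ventral, slightly nasal:
a shallow anchor reproduces the qualitative map (about -45/+45 degree
deviations in VN/VT with magnitude growing away from the optic nerve,
near-horizontal preferred axes in central ventral retina, near-vertical in
temporal retina), whereas a deep anchor would place the sampled band where
all tangents are nearly horizontal. A `condition` tag (NR / B2KO / DR)
exists for study designs comparing rearing conditions; it changes nothing
by default, reflecting the finding that the map is condition-invariant,
with `condition_effect` as an optional effect-size hook for power
analyses.

What the generator does *not* emulate: optics and indicator biophysics,
eye-to-flat-mount distortion, spatial correlations of noise, cell-body
overlap, or within-class amplitude diversity. Passing tests therefore
demonstrate correctness of the analysis under the stated statistical
structure, not robustness to every property of real recordings.

## The concentric map model

The model says preferred orientation at a retinal point is the tangent of
the concentric circle/ellipse through that point, for a family anchored at
`(x_c, y_c)` with fixed horizontal/vertical radius ratio. Tangents are
computed from the direction vector `(-x_r^2 (y - y_c), y_r^2 (x - x_c))`
via `atan2`, which survives vertical tangents; the analytic slope form
`-(y_r^2 (x - x_c)) / (x_r^2 (y - y_c))` is kept as a cross-check in tests
wherever it is finite.

`predicted_angle_curve()` follows the classical construction: sweep radii
(default 100-2000 um in 25-um steps), intersect each family member with a
sampling axis (exact quadratic roots), and take tangent angles at the
forward-ray intersections. When the anchor is off the axis a family member
can cross the forward ray twice; both points are kept, since the near
branch is needed to cover small distances. `predicted_deviation_at()` is
the equivalent direct evaluation — every axis point belongs to exactly one
family member — sampled uniformly in distance, which is what curve fitting
wants (the sweep's intersection points are sqrt-spaced and leave gaps near
tangency).

**Fitting.** Measured deviation-vs-distance curves (per-FOV double-angle
circular means against FOV distance from the optic nerve) and model curves
are both reduced to least-squares quadratics; the score is the integral of
the absolute difference of the two quadratics over the measured distance
range (trapezoid on a 1-um grid), summed over the VN and VT axes. The
anchor and aspect are found by a deterministic grid search (default:
anchor x in -400..400 um by 100, y in -650..-50 by 50, aspect 1.00-1.20 by
0.01) — the score surface is cheap and reproducibility beats continuous
optimization. When the measured curves carry FOV center coordinates, the
model is evaluated at those actual locations rather than idealized
on-axis points: FOVs scatter around the axes, and evaluating both curves
at the same locations removes a several-degree systematic that would
otherwise bias the fit. Two known small effects remain: per-FOV circular
means average the tangent field over the 425-um FOV footprint while the
model is evaluated at the center, producing a slight (~0.01) downward bias
in recovered aspect; and anchor-depth and aspect are partially degenerate
along the diagonal axes, so aspect recovery needs many FOVs (the
acceptance analysis uses 100 FOVs of 50 overrepresented OS cells,
mirroring pooled multi-condition datasets; with only ~20 FOV-level curve
points per axis the fit can slide one grid step along the degeneracy).

## Numerical and degenerate-input choices

- Angles at boundaries: orientations are folded into [0, 180) everywhere;
  180 read from a file becomes 0 with a warning.
- All-zero peak vectors raise an undefined-tuning error; flat response
  matrices give QI 0 + flag; flat ON-OFF features are flagged degenerate.
- Circular means with resultant below 0.1 (e.g. an orthogonal 50/50
  mixture in a flow-field bin) report an undefined (NA) axis rather than
  an arbitrary one.
- Flow-field bins with fewer than 5 cells are masked; histogram bins are
  10 degrees, the flow grid 100 um — display-scale choices, configurable.
- The more/less-ventral regional split uses the median FOV center height
  by default; the split rule is a parameter.
- k-means ties and restarts: best of `restarts` by within-cluster sum of
  squares with a fixed seed, so chosen k is reproducible.
- The von Mises sampler is the Best-Fisher rejection algorithm; kappa =
  Inf short-circuits to the mean (used for noiseless ground truth).

## Problem sizes used by the test suite

The suite runs at desk scale, chosen so the full run stays within a few
minutes while keeping each check statistically meaningful: 2000 null cells
x 1000 permutations for the calibration check; 1500 OS cells for subtype
selection; 5000 overrepresented OS cells across 100 FOVs for aspect
recovery; 10^4 random ellipse/point draws for the tangent oracle. The
acceptance script (`scripts/acceptance.R`) re-derives its quantities from
scratch at the same scales.

## Known limitations

- The planar model ignores spherical eye geometry and flat-mount
  relaxation cuts; it describes the map in flat-mount coordinates only.
- Orientation is reported in motion-axis space; bar-long-axis conventions
  differ by 90 degrees.
- With 8 stimulus directions, the vector-sum preferred orientation of a
  sharply tuned cell aliases slightly (harmonics beyond the grid fold
  back); the error is bounded well inside one 22.5-degree half-step at
  the generator's concentrations and vanishes for on-grid preferences.
- Aspect-ratio identifiability from two diagonal sampling axes is weak at
  small FOV counts (see above); sampling ventral and temporal retina
  directly would pin it better, and the map statistics support those
  sectors (`V`, `T`) for such designs.
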