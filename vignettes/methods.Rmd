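---
title: "Methods: comparing acoustic and satellite telemetry estimates of space use"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparing acoustic and satellite telemetry estimates of space use}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trackcompare)
```

## The problem

Passive acoustic telemetry and Argos satellite telemetry are both used to
quantify the space use of coastal marine animals, but they observe movement
very differently. An acoustic array logs sub-minute detections whenever a
tagged animal passes within a receiver's detection range, so its spatial
support is the array and its accuracy the detection radius (one to a few
hundred metres). Argos tags yield a handful of surfacing-limited fixes per
day whose errors range from under 250 m (location class 3) to many
kilometres (classes A/B). `trackcompare` implements the full pipeline needed
to compare the two: detection processing and centre-of-activity (COA)
positioning on the acoustic side; location-class prefilters, outlier
filtering and continuous-time state-space smoothing on the satellite side;
dynamic Brownian bridge occurrence distributions (ODs) and
autocorrelation-informed kernel range distributions (RDs) for both; and
overlap, coverage, Bayesian and cost comparisons. A synthetic-data module
generates every input with known ground truth.

## Planar frame and grids

All analysis happens in metres in a single ellipsoidal transverse-Mercator
frame (`tm_projection()`, default central meridian 79°W, scale 0.9996). The
study extent (tens of km) is far smaller than a projection zone, so scale
distortion is order 1e-4 and ignored. The inverse projection is computed by
Newton iteration on the forward map, which makes round trips close to well
under a millimetre. Probability surfaces live on cell-centre-registered
grids; contour regions are the smallest set of highest-density cells whose
cumulative mass reaches the level, with all cells tied at the threshold
density included so the result cannot depend on iteration order. Region
areas are cell counts times cell area. The union of detection-range disks is
computed by strip integration with exact one-dimensional interval unions — a
deterministic, resolution-independent method whose error against the closed
forms is well below 0.1% — and point-in-coverage tests use exact distances,
so outside-of-coverage fractions are limited only by the UD grid resolution.

## The synthetic scenario

The generator emulates a two-island lagoon system: two elongated islands in
an L with a semi-enclosed lagoon at the corner, fringing reef along shores,
a seagrass bed to the south, sand elsewhere. Its defaults are the study
conditions every test and the acceptance script use:

* **Movement** — an exact-discretization Ornstein–Uhlenbeck position process
  (optionally OUF with autocorrelated velocities) around a home centre, with
  stationary per-axis variance `sigma2 = 4e6` m² (a ~2 km home-range scale,
  consistent with juvenile green turtle range distributions of tens of km²)
  and `tau_pos = 2` days (a few range crossings per fortnight). Steps onto
  land are redrawn up to 100 times, then held. Exact discretization removes
  time-step bias, which the variance/autocorrelation recovery tests rely on.
* **Array** — 63 receivers; random placement is habitat-weighted
  (reef/seagrass/lagoon over open sand, 12:1), the way real coastal arrays
  ring islands and foraging beds. Receivers carry the detection kernel of
  their habitat: logistic detection probability with d50 = 185 m and
  d01 = 520 m over reef/seagrass, 350 m and 1100 m over sand/lagoon.
* **Acoustic tags** — transmission delays uniform on 50–130 s (mean 90 s,
  hence ~960 transmissions/day); every transmission is detected
  independently by every receiver with kernel probability at the current
  distance.
* **Argos tags** — fixes from a Poisson process at 3/day (the fix-rate model
  is a modelling choice; the method only states a mean rate), location
  classes drawn so LC 3+2 ≈ 6% and LC 0–3 ≈ 12% of fixes, and isotropic
  Gaussian errors of 150/350/1000/2500 m for LC 3–0, 2500/5000 m for A/B and
  10 km for the nominally invalid LC Z.

What the generator does **not** emulate: diel and tidal behaviour, depth and
surfacing (folded into the Argos rate), spatially varying detection
probability within a habitat class, receiver clock drift, and heavy-tailed
Argos errors. Tests passing on this generator therefore demonstrate the
pipeline's correctness and the direction of method differences under
Gaussian errors and stationary foraging movement — not calibrated agreement
with any particular field dataset.

## Acoustic pipeline

Raw detections pass five filters in order: exact duplicates; detections
before release; a 24 h post-release acclimation window; user-supplied
blackout windows (e.g. a 57 h receiver-maintenance outage); and finally
lone detections, with no other detection of the same tag within ±1 h.
"Double detections" are read as exact duplicates (same tag, receiver,
second); the lone rule is evaluated last, across all receivers.

Detection kernels are binomial logistic regressions of detected/expected
against distance (via `glm`), with d50 = −a/b and d01 = (logit(0.01) − a)/b.
Each detection is then re-assigned to a random position within its
receiver's range: bearing uniform, radius from a density proportional to
d·p(d) on [0, d01]. The factor d makes the prior uniform in area — a flat
kernel yields uniform points in the disk — and is switchable to plain p(d)
weighting (`radius_weight = "distance"`) since the weighting convention is
genuinely ambiguous. Truncation at d01 defines "within detection range".
Land points are redrawn (cap 1000).

COAs are arithmetic means of relocated positions in 30-min bins aligned to
clock half-hours (UTC) and labelled at bin midpoints; clock alignment keeps
bins comparable across tags. The COA error radius is the mean
receiver-to-relocation distance of the contributing detections. A property
worth knowing: for a stationary animal near one receiver the mean COA
converges to the receiver, not the animal — the method is receiver-centred
by construction, and a test documents this bias.

## Satellite pipeline

Prefilters remove LC Z, duplicate transmissions (keeping the better class,
3 > 2 > 1 > 0 > A > B), the 24 h acclimation window, and implausible leading
fixes whose implied speed from the release position (timed from the end of
the acclimation window) exceeds 2 m/s. The speed-distance-angle filter then
iterates to a fixed point: fixes faster than 2 m/s on both adjacent
segments are removed, then spikes with internal angle < 15° and a step
> 1500 m, or angle < 25° and a step > 3000 m. The two angle/distance pairs
implement the published ranges as a tight and a loose spike rule; both are
configurable.

The state-space model is a continuous-time correlated random walk: per axis
a (position, velocity) state with Ornstein–Uhlenbeck velocity
(autocorrelation β, intensity σ), exact transition matrices for irregular
intervals, and Gaussian measurement error fixed per location class — the
class-sd map is configuration, not an estimate. β and σ are estimated by
maximizing the Kalman-filter likelihood from three starting points, with β
constrained to timescales between 1 s and 10× the track span and σ to
[1e-6, 100]; a brute-force joint-Gaussian likelihood cross-checks the filter
on small tracks to 1e-6. The Rauch–Tung–Striebel smoother yields positions
and per-axis standard errors at the observation times; on-land locations are
removed, then locations whose smaller SE (se_min, the dBBMM error input)
exceeds 3 km. When true movement is small relative to the class errors the
likelihood genuinely favours a near-stationary fit and most smoothed
locations can fall on land or collapse — the affected individual is then
excluded exactly as field individuals with too little data are.

## Occurrence distributions (dBBMM)

The Brownian bridge positional variance at interpolation fraction α of a
bridge of duration T is

    s²(α) = T σm² α(1−α) + (1−α)² δa² + α² δb²,

with δ the endpoint location errors (COA error radius or se_min). The
motion variance σm² is estimated by leave-one-out likelihood of the interior
even-position observations, each predicted from its neighbours; the left-out
point's own error variance is added to s²(α) in that likelihood, without
which σm² absorbs observation noise (a bias verified in testing). The 1-D
search runs on the log scale over [1e-8, 1e4] m²/s, and a grid-search oracle
test pins the optimizer to within one grid step.

Behavioural segmentation slides a window (acoustic: 49 observations ≈ 24 h
of 30-min COAs, margin 15; satellite: 13 observations ≈ 24 h at the ~2 h
median interval, margin 3) and compares a one-variance model against every
two-variance breakpoint outside the margins by BIC — BIC rather than AIC to
control the multiplicity of candidate breakpoints. Each location's σm² is
the mean over all windows covering it (averaging is deterministic;
"most-recent window" is not). Tracks shorter than the window get a single
global variance, which also makes the dynamic estimator collapse exactly to
the static Brownian bridge — an equivalence tested to L1 < 1e-6.

Rasterization splits the track into bursts at gaps > 24 h (no bridge spans
a gap), integrates each bridge with 10 Gauss–Legendre nodes over α
(doubling the nodes changes areas < 0.5%, tested), weights bridges by
duration, uses exact Gaussian cell-edge probabilities, and normalizes to
total mass 1. Default cells are 50 m (acoustic) and 100 m (satellite),
roughly the positional-error scale; the grid pads the track extent by 3×
the largest bridge sd. ODs require at least `min_locations` (49 for
acoustic) observations, else an explicit insufficient-data error that the
pipeline logs and skips. Contours are computed before land clipping; land
cells are then removed and areas reported without renormalization (a
`renormalize` switch exists on the surface clipper for sensitivity work).

## Range distributions (CTMM + weighted kernel density)

Candidate movement models — IID, OU, OUF — are fitted by exact Gaussian
maximum likelihood on the (possibly irregular) timestamps, deliberately
without a measurement-error term, and selected by AIC. IID and OU use the
exact conditional factorization; OUF uses the full autocovariance matrix
C(h) = σ²(τp e^{−h/τp} − τv e^{−h/τv})/(τp − τv) with τv constrained below
τp. For long tracks the candidates can be fitted on an evenly thinned
subset (`max_n`); all candidates share the thinned data so AIC comparisons
remain valid, and the full data still drive the density estimate.

The effective sample size is duration/τp (range crossings) for OU/OUF and n
for IID; N_eff ≤ 1 attaches a low-sample warning rather than failing. The
range density is a Gaussian kernel estimate whose bandwidth is the
stationary scale inflated for autocorrelation, h² = σ̂²·N_eff^{−1/3} per
axis, with per-location weights proportional to the time spanned around
each location (inverse sampling intensity, normalized to sum to n) so
irregular sampling does not bias the estimate; under exactly regular
sampling the weights are equal. This is a deliberately simplified stand-in
for the full optimally-weighted autocorrelated kernel estimator: it
implements the two defining ideas (autocorrelation-adjusted bandwidth,
irregularity weights) explicitly, and its deviation from a plain
reference-bandwidth KDE in the IID limit is bounded at 10% in tests, with
the 95% area within 25% of the Gaussian closed form 5.99·π·σ² on OU
simulations at N_eff ≥ 30. The density is masked to water and renormalized
*before* contouring (the land boundary is part of the estimator here,
unlike the OD's post-hoc clipping).

## Comparisons

Bhattacharyya affinity is Σ√(p·q) on a common grid (the finer cell size,
mass-conserving resampling). By default BA is computed on level-truncated,
renormalized surfaces, since overlap "for both 95% and 50% UDs" is read as
comparing the contoured distributions; `level = NULL` gives the
whole-surface BA. The Bayesian two-group comparison models each group of
areas as t-distributed with its own mean and sd and a shared normality
parameter ν: means ~ Normal(pooled mean, 1000·pooled sd), sds ~
Uniform(pooled sd/1000, pooled sd·1000), ν − 1 ~ Exponential(1/29), sampled
with JAGS in two seeded chains. It is run as an unpaired comparison (the
package convention for this model family) on untransformed areas, with a
log switch; JAGS exposes no Metropolis acceptance rate, so the reported
chain diagnostics are split R-hat and effective sample size. Coverage
analysis builds disk-union coverages at the d50 and d01 radii plus the
receiver MCP and reports outside fractions per UD region; d01 coverage
always contains d50 coverage, so outside fractions are ordered. Duration
matching trims both streams to their common active window and excises
blackout windows from the satellite stream too; an optional exploratory
rerun restricts satellite fixes to the 1% coverage region
(`restrict_to_coverage()`).

Whether the printed array-coverage areas of a field study include land is
generally unstated; `union_of_disks()` reports the geometric union and the
clip-to-water question is left to the caller (the coverage object supports
point membership, so a water-clipped fraction is one mask away).

## Cost model

Satellite scenarios cost n·(tag + tariff·months/6); acoustic scenarios cost
maintenance(months) + n·tag, plus a fixed installation cost for a new
array. Defaults (Argos tag $1,925; Fastloc $5,025; acoustic $525; tariff
$378/6 mo; maintenance $10,800/6 mo and $21,200/12 mo; installation
$90,200) reproduce every internally consistent cell of the standard
scenario table; the 12-month maintenance is deliberately a free parameter
because published 12-month costs are not a doubling of 6-month costs.
Published acoustic cells at n = 20 imply a higher per-tag cost (~$545) —
possibly a bulk labour term — and are intentionally not modelled.

## Problem sizes and numerical choices

The test-suite and acceptance scenarios run 16-day cohorts of 3 individuals
at 60 s movement steps — sizes chosen so a full run finishes on one CPU in
minutes while keeping ≥ 49 COAs and ≥ 13 post-SSM satellite locations per
healthy individual. Study-scale durations (~4 months) only make the
comparisons easier, at proportional cost. Other numerics: rejection
sampling for relocation radii with a 0.1%-inflated envelope; smoother
prediction covariances regularized by 1e-9 of their largest diagonal before
inversion; bridge sds floored at 1 mm; probability-mass assertions at 1e-9.

## Known limitations

* Argos errors are isotropic Gaussian per class; real errors are
  heavy-tailed and elliptical, so the satellite side of the comparison is,
  if anything, optimistic.
* The weighted-kernel range estimator is the simplified form described
  above, not the full optimal-weight solution.
* The Bayesian comparison treats individuals as unpaired groups even though
  each animal carries both tags; a paired model would be more sensitive.
* COA error radii understate positional uncertainty when detection
  probability fluctuates in time, as it does in the field.
* The cost model is a linear parametric family; cells reflecting
  non-linear bulk effects are out of scope by design.
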