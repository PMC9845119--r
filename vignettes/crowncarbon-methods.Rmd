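---
title: "From crown masks to carbon: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From crown masks to carbon: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crowncarbon)
```

crowncarbon turns binary tree-crown segmentation rasters — the typical
output of a deep-learning crown mapper applied to very-high-resolution
aerial imagery — into per-tree stem diameter, biomass and carbon estimates,
and per-hectare maps of tree density, canopy cover and carbon density. This
vignette explains the model chain, the assumptions behind each stage, the
tunable parameters, and the numerical choices where the design was open.

## The problem

A segmentation model classifies each pixel as crown or background. Two
post-processing problems follow. First, neighbouring trees touch: a single
connected foreground blob often contains several crowns, so instances must
be separated before anything can be counted. Second, a crown is only a
proxy for carbon: field-calibrated allometric equations are needed to step
from crown diameter (CD) to stem diameter (DBH) to aboveground biomass
(AGB) and carbon (AGC). Both steps carry uncertainty that has to be
reported alongside the maps.

## Crown separation: detect centre and relabel (DCR)

`dcr()` composes four deterministic stages.

**Distance transform.** Every foreground pixel gets its exact Euclidean
distance (pixel units) to the nearest background pixel. The image border is
treated as adjacent to background, so crowns truncated by a tile edge get
finite distances; tiles can therefore be processed independently. The
transform is the exact two-pass lower-envelope algorithm (squared parabola
envelopes per row and column), implemented in compiled code because it is
also reused for crown dilation.

**Centre detection.** Crowns are assumed round, so their interior distance
field peaks near the centre. A pixel is a centre candidate when an
`m` × `m` maximum filter leaves its distance value unchanged. Plateaus —
8-connected groups of candidates, common where the distance field is flat —
are merged to a single centre, represented by the smallest row-major pixel
of the group; row-major choice is arbitrary but deterministic. `m`
(default 3 px) bounds the smallest object that can be separated; with
0.25 m pixels, `m = 3` resolves crowns down to the 0.25 m² minimum mapped
size. Larger `m` merges near-by maxima and is appropriate when the smallest
crown of interest is larger.

**Relabelling.** Each foreground pixel `x` is assigned to the centre `c`
minimising

d(x, c) = ‖x − c‖₂ + λ · B(x, c),

where `B(x, c)` counts background pixels on the Bresenham line from `c` to
`x` (endpoints excluded). The additive penalty keeps a crown from claiming
pixels across a gap. λ defaults to the grid diagonal in pixels: any
assignment whose line crosses even one background pixel is then strictly
worse than any gap-free assignment, whatever the Euclidean distances
involved, while λ = 0 recovers plain nearest-centre (Voronoi) labelling.
The penalty form (additive), the line discretisation (Bresenham, endpoints
excluded) and the tie rule (smallest centre index) were open choices fixed
for determinism; all are exposed as configuration. The implementation
visits centres in increasing Euclidean distance and stops once the plain
distance exceeds the best penalised distance found — an exact pruning,
since the penalty is non-negative.

**Hole filling.** Boundary-weighted segmentation leaves artificial gaps
inside large crowns. Background regions not 4-connected to the scene
exterior and bordered (8-neighbourhood) by exactly one label are converted
to that label. Holes bordered by two or more labels are left untouched, so
filling never merges neighbouring crowns. The 8-neighbour border census is
deliberately conservative: a hole that touches a second label even
diagonally stays background.

Every stage is checked against an independent brute-force oracle
(all-pairs distance minimum, exhaustive window maxima, exhaustive
penalised assignment, flood-fill census) on randomly generated scenes; the
pipeline output is required to be *identical*, not merely close.

## Crown geometry and canopy cover

`extract_crowns()` reports, per instance, the pixel count, area
(count × pixel²), the crown diameter of the equal-area circle
CD = 2·√(area/π), and the world-coordinate centroid. Crowns below
0.25 m² — the smallest crown reliably visible in 0.25 m imagery — are
dropped.

Boundary-weighted models systematically shrink predicted crowns by
emphasising inter-crown gaps; a calibration against manual delineations
puts the shortfall at 27 % of crown area. For canopy cover each crown is
therefore buffered outward by r = (√1.27 − 1)·CD/2, growing its area by
approximately 27 %, and the buffered crowns are dissolved (per-pixel
maximum) into continuous cover. An alternative reading scales the
*diameter* by 1.27 (buffer 0.135·CD), which yields ~13 % more cover; the
area interpretation is the default and the other is available via
`mode = "diameter"`. Note the asymmetry with the allometry below, which
applies the literal CD × 1.27 inside the natural-forest equation: each
usage reproduces the convention under which its calibration was
established.

Buffering is raster-based (no polygon engine is involved): the compiled
distance transform gives each pixel its distance `d` to the nearest crown
pixel centre, and the pixel's covered fraction is
clamp(1/2 + r − max(0, d − 3/8), 0, 1). The 3/8 px offset is the
orientation-averaged correction between pixel-centre distances and the
true smooth crown boundary (1/2 px for axis-aligned boundaries, about
1/4 px for diagonal ones); with it, the dissolved area of an isolated
rasterized disc reproduces the analytic buffered-circle area to about 1 %
for radii ≥ 8 px, where hard thresholding misses by 3–8 % because typical
buffer radii are only one or two pixels. Cover is therefore a *fractional*
raster in [0, 1]; `cover_mask()` thresholds it at 0.5 when binary geometry
(e.g. connectivity of cover features) is wanted, and per-hectare cover
sums the fractions.

`aggregate_hectares()` bins tree centroids into half-open 100 m cells
[x, x+100) × [y, y+100) — half-open so boundary trees are counted exactly
once — and reports tree density (trees/ha), canopy cover (%), and carbon
density (MgC/ha, from the per-tree AGC sums). Trees outside the grid are
kept in an explicit overflow bin, never dropped silently. The centroid
alone decides a tree's cell (and later its land-cover class): a single
deterministic assignment per tree, at the cost of ignoring crowns
straddling boundaries.

## Allometry

Stem diameter is predicted from crown diameter with major axis (MA)
regression — the symmetric errors-in-both-variables line, appropriate
because CD and DBH are both measured with error. The slope is the leading
eigenvector of the sample covariance:

slope = (Syy − Sxx + √((Syy − Sxx)² + 4·Sxy²)) / (2·Sxy).

Two facts about MA matter for interpreting fits. It is *not* equivariant
under rescaling one axis (that property belongs to standardised MA), so
units must match the calibration. And when the noise is actually confined
to one axis, or the predictor spread is small relative to the noise, the
MA slope is biased upward and the residual spread inflated; recovery
tests therefore sample calibration crowns across a wide diameter range
(for the log-scale fit, lognormal(log 4, 1) m), where the estimator is in
its consistent regime.

Two model forms are supported, with defaults from established
calibrations:

* **Linear MA** (trees outside natural forest):
  DBH (cm) = −4.665 + 5.102 · CD (m). The line crosses zero near
  CD = 0.914 m, so crowns between the 0.25 m² minimum and ~0.66 m² get a
  non-positive DBH; such trees receive zero biomass and the flag
  `below_allometry_domain` rather than a negative estimate.
* **Logarithmic MA with Baskerville correction** (natural forest):
  DBH = exp(1.154 + 1.248·ln(CD·1.27)) · exp(σ²/2) with σ = 0.3315. The
  CD × 1.27 pre-scaling compensates crown shrinkage in dense canopies; the
  exp(σ²/2) factor corrects the downward bias of the naive exponential
  back-transform. σ is the standard deviation of *vertical* residuals in
  log space (orthogonal residuals were the alternative; vertical is what
  the back-transform correction assumes).

The fitting protocol `fit_half_sample_average()` fits four random
half-samples and averages coefficients, stabilising the fit against
sampling variation; the seeds (default 1–4) are stored in the model and
written to the plain-text model files, which round-trip coefficients
bit-exactly at %.17g precision.

Biomass follows from DBH by land-cover class:

* savannas and shrublands: AGB = 0.091 · DBH^2.472 (kg, East-African
  non-forest calibration);
* plantations (Eucalyptus and other), farmland, urban/built-up:
  AGB = 0.202 · DBH^2.447 (destructive plantation samples);
* natural forest: the pantropical moist-forest form
  AGB = exp(1.803 − 0.976·E + 0.976·ln ρ + 2.673·ln DBH −
  0.0299·(ln DBH)²), with wood density ρ defaulting to 0.54
  (abundance-weighted average for Rwandan natural forest) and the
  environmental-stress scalar E a **mandatory explicit input** — the
  gridded E layer varies by site and a silent default would hide a real
  modelling decision. (A scalar per scene is supported, not the gridded
  layer itself.)

Carbon is AGC = 0.47 · AGB throughout. The class → equation routing is a
plain list (`default_allometry_table()`) and can be overridden entry by
entry.

## Stratification

`assign_class()` gives each tree the class of the first land-cover feature
(in file order) containing its centroid; first-feature-wins also resolves
boundary and overlap cases deterministically. Trees outside every feature
take a mandatory `default_class` and the flag `outside_landcover` —
mandatory because synthetic or clipped layers legitimately leave gaps, and
the caller should own that decision. Both GeoJSON polygon layers and
categorical rasters (with a value → class map) are accepted; the six
classes are validated at load and unknown values are rejected.

## Uncertainty

Three complementary measures:

* `bias_relative()`: mean of (obs − pred)/obs × 100 — per-plot relative
  systematic error.
* `bias_summed()`: |Σ(obs − pred)| / |Σ obs| — error of aggregate totals,
  sign-symmetric.
* `national_uncertainty()`: Σ area-weight × |class bias|. Magnitudes are
  used because over- and under-predicting classes must not cancel in a
  headline figure; the result always lies between the smallest and largest
  class bias magnitude.

`ensemble_uncertainty()` propagates calibration-sampling uncertainty: four
CD–DBH models are fitted on random half-samples (fixed, recorded seeds),
each predicts carbon for every tree, carbon is aggregated per
(land-cover class, hectare cell), and the per-cell rRMSE across the runs
(sd/mean, sample sd with k − 1) is averaged per class. The per-cell
formula across ensemble members was an open choice; it is recorded in the
output (`rrmse_definition`). A noiseless calibration table yields four
identical fits and exactly zero rRMSE; rRMSE grows monotonically with the
calibration noise. Degenerate fits (zero covariance) are excluded and
counted, and fewer than two usable runs is an error.

`plot_level_eval()` sums predicted AGC of trees whose centroids fall in
each field plot and reports the pairs plus rRMSE and both bias forms;
plots without predicted trees are retained at prediction 0, because
omitting them would bias the comparison optimistically.

## The synthetic-data generator

`make_scene()` emulates the *output* of a crown segmentation model — not
imagery: circular/elliptical crowns with lognormal radii
(meanlog = log 1 m, sdlog = 0.6 by default, placing most crowns in the
0.25–15 m² range that dominates real tree populations in agricultural
mosaics), a configurable fraction placed touching or overlapping an
earlier crown (the clumps DCR must separate), and the rest placed disjoint
by rejection sampling. Ground truth gives contested pixels to the
later-placed crown — an arbitrary but fixed convention, since the
generator's purpose is evaluating separation, not occlusion modelling.
When a crowded grid cannot host a sampled radius, the radius shrinks by
10 % and placement retries, so the effective radius distribution is
truncated by feasibility; this keeps dense configurations generable from
any seed. All generators are pure functions of their configuration,
seed included.

What the generator does *not* emulate: irregular crown shapes, the spatial
error structure of a real segmentation model (over-/under-segmentation,
boundary noise), understory, or vertical layering. Passing tests on
synthetic scenes therefore demonstrate algorithmic correctness —
separation, conservation, determinism, parameter recovery — not remote-
sensing accuracy on real imagery, which requires field calibration.

`make_allometry_table()` draws CD, computes noiseless DBH/AGB from the
configured generating equations, and adds Gaussian (one- or two-axis) or
median-preserving lognormal noise, keeping the noiseless truth columns so
recovery tests can compare against the generating values.

## Numerical and interface choices

* Rasters are exchanged as ESRI ASCII grids (text, georeferenced,
  deterministic to write); vectors as GeoJSON; tree tables as CSV with
  %.12g numerics so identical runs produce byte-identical files. The
  in-memory containers are plain matrices with pixel size, top-left origin
  and an opaque CRS tag carried through unmodified.
* All pixel work is done in (row, col) with row 1 at the north edge;
  world coordinates use pixel centres.
* Degenerate inputs fail loudly: non-binary masks, even `m`, negative
  penalties, empty centre sets with non-empty foreground, zero
  observations in bias denominators, mismatched strata, unknown classes.
* Problem sizes in the test-suite and the acceptance script (scenes of
  36–800 px, 10⁴-tree calibration tables, 4-ha grids) were chosen so the
  statistical recovery targets are well inside their asymptotic regime
  while a full run stays interactive.

## Known limitations

* DCR assumes roughly round crowns; elongated or lobed crowns can yield
  several centres and over-segmentation. `m` trades this against merging
  small neighbours.
* The 27 % expansion and all equation coefficients are calibration
  constants for one sensor/model/region combination; reuse elsewhere
  requires refitting (`fit_major_axis()`, `fit_log_ma_baskerville()` take
  any paired sample).
* E is a scene scalar here, not a gridded covariate.
* Carbon estimates are overstory-only by construction: trees invisible
  from above are absent from the mask and hence from the totals.
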