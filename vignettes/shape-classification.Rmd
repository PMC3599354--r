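---
title: "Curvature-based shape classification of 3D skin-injury models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Curvature-based shape classification of 3D skin-injury models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(injuryshape)
```

## The problem

Forensic pathology sorts skin injuries into morphological categories —
abrasions, incised wounds, gunshot entry wounds, strangulation marks,
patterned injuries — because the category points to the causing instrument.
`injuryshape` implements an automated version of that judgement for 3D
surface scans: a triangle mesh of a centrally located lesion on an otherwise
flat patch is encoded as a fixed-length vector of curvature-stratified shape
descriptors, the vector is reduced to its most discriminative elements, and
a regularized discriminant classifier assigns the lesion to one of six
classes under stratified 6-fold cross-validation. Because no scan data of
this kind are publicly deposited, the package also ships a seeded generator
of synthetic lesion meshes so the entire pipeline is testable end to end.

## The pipeline

### Mesh model and normalization

A mesh is a set of 3D vertices plus triangle connectivity (`triangle_mesh`),
read from OBJ or PLY via `read_mesh()`. Before any descriptor is computed the
patch is translated so its centroid sits at the origin and scaled by one
common factor so that the larger of its x- and y-extents equals 1
(`normalize_unit_square()`). Two choices here were genuinely open and are the
package's own:

* **Centering.** Centroid-to-origin makes "concentric spheres around the
  origin" well defined and puts the lesion (which dominates the curvature
  mass) near the center of the sphere series.
* **Uniform scaling from the larger planar extent.** A single scale factor
  for all three axes preserves every distance ratio, hence the patch's shape;
  an anisotropic fit to the unit square would distort curvature and make the
  fixed band thresholds meaningless.

### Curvature estimation

`estimate_curvature()` estimates each face's Weingarten matrix (second
fundamental form) by least squares from the variation of vertex normals
along the face's three edges, then averages face tensors onto vertices after
rotating each tensor into the vertex tangent plane. Averaging weights are the
mixed Voronoi areas of the face corners (the standard choice for this
estimator); uniform weights are available via `weighting = "uniform"` because
the appropriate weighting is not uniquely determined — on smooth test
surfaces the two agree to within a couple of percent. The sign convention is
convex positive: a unit sphere with outward normals has mean curvature +1, a
pit is negative, and saddle points have negative Gaussian curvature
(*hyperbolic* points).

Curvature is computed **after** unit-square normalization. The curvature-band
thresholds below are fixed numbers, and only in a size-normalized frame are
they comparable across specimens; in raw millimetre units a 10x larger
specimen would have 10x smaller curvatures. Boundary vertices are retained
with one-sided estimates: lesions are interior by construction, and the flat
band absorbs boundary effects.

### Curvature bands and descriptors

`partition_curvature()` assigns every vertex to one of 13 bands of mean
curvature: a flat band (|mc| &le; 0.17, discarded), six convex bands (from
"little convex", 0.17 &lt; mc &le; 0.25, up to "strongly convex", mc &gt;
0.8) and six mirrored concave bands. The flat band is symmetric,
|mc| &le; 0.17 — the threshold value was originally chosen by sweeping the
flat cutoff over |mc| in [0, 0.3] and inspecting which vertices survive, a
procedure that only makes sense for a symmetric interval. At the threshold
itself the flat band wins.

For each of the 12 non-flat bands, `shape_vector()` computes 107 descriptors:

* `d0–d39` — histogram of all inter-vertex Euclidean distances in 40 equal
  bins over [0, 2] (normalized units), last bin closed and clipping
  overflow;
* `d40, d41` — max/mean and max/median distance ratios;
* `d42, d43` — volume and surface area of the band's 3D convex hull;
* `d44` — max/mean histogram frequency;
* `d45` — band vertex count;
* `d46–d55` — cumulative counts inside 10 concentric spheres around the
  origin, radii j/10 of the mesh's largest vertex norm;
* `d56–d95` — DFT magnitudes of the distance histogram;
* `d96–d105` — DFT magnitudes of the sphere-count series;
* `d106` — number of hyperbolic points.

Empty bands contribute zero blocks, so every mesh maps to exactly
12 x 107 = 1284 elements in a fixed order.

Numerical choices worth stating: the histogram range is fixed at [0, 2] for
all meshes (a per-mesh range would destroy cross-specimen comparability);
"the curvature histogram" feeding `d56–d95` is read as the 40-bin distance
histogram of the curvature band, the only 40-length sequence defined per
band (the alternative reading — a histogram of mc values — has no defined
binning anywhere); Fourier output is the magnitude spectrum with the DC term
first; bands larger than 2000 vertices are reduced by a seeded uniform
subsample before the O(n²) pairwise-distance work, while `d45` always
reports the true band size; hulls of degenerate (coplanar or < 4 point)
sets are (0, 0) by contract, not an error.

The 3D convex hull is an incremental hull written for this package (no
installed hull routine was available). Grid-sampled height fields produce
large exactly- and nearly-coplanar point sets — the classic hard case for
incremental hulls — so insertions are validated: a point whose visibility
horizon fails to form a simple closed loop is first retried with the
coplanar band included, and if any insertion still cannot be committed the
whole hull is rebuilt once with a deterministic sub-tolerance joggle
(1e-7 of the bounding-box diagonal). Clean inputs never take the joggle
path, so the closed-form oracles (cube, tetrahedron) are exact, while
degenerate grids agree with an independent reference implementation to
about seven significant digits and are stable under perturbations at the
1e-9 level.

### Descriptor reduction

`select_descriptors()` filters the 1284 columns on **training data only**, in
three stages, with the default thresholds the method is defined with:

1. **Pairwise SNR** (threshold 3.00): for each of the 15 class pairs,
   |difference of class means| / max(class standard deviations); a
   descriptor is kept when its *maximum* over pairs reaches the threshold.
   Max-over-pairs (rather than, say, min) is deliberate: descriptors that
   separate even one pair strongly carry usable signal for a quadratic
   discriminant, and the mirror-image alternative would discard pair-specific
   discriminators entirely.
2. **Moment filter** (sample excess kurtosis &le; 16.0, |sample skewness|
   &le; 13.4, maxima over the six classes; zero-variance groups count as 0).
   Kurtosis is the *excess* form and skewness enters in absolute value —
   the choices under which the thresholds sit in a meaningful range for
   groups of n = 18.
3. **Kendall tau-b** (threshold 0.95): a greedy pass in order of decreasing
   SNR drops any candidate whose |tau-b| with an already-kept descriptor
   exceeds the threshold, so near-duplicates lose to their higher-SNR
   partner. Tau-b is computed by an exact vectorized sign-matrix
   crossproduct (verified against `stats::cor(method = "kendall")` in the
   test suite) because the reference implementation is two orders of
   magnitude slower at this column count.

If nothing survives, `select_descriptors()` raises a typed error. Inside
`run_cross_validation()` the caller chooses: propagate (default), or fall
back to the 10 highest-SNR descriptors (`on_empty = "top"`, recorded in the
fold's report). The fallback exists for the noise study below — under
extreme perturbation *no* descriptor legitimately passes SNR 3, yet the
protocol still needs a defined classifier to document the decay to chance.

### Classification

`shape_rda()` fits regularized discriminant analysis after standardizing
each descriptor to mean 0 / sd 1 (training statistics, stored in the model
and re-applied to test data). Class covariances are shrunk twice:

$$\Sigma_k(\lambda) = (1-\lambda)\,S_k + \lambda\,S, \qquad
\Sigma_k(\lambda,\gamma) = (1-\gamma)\,\Sigma_k(\lambda) +
\gamma\,\tfrac{\mathrm{tr}\,\Sigma_k(\lambda)}{p}\,I$$

with pooled covariance S. The order — pooled first, then identity — and the
scaled-identity target (Friedman's form, rather than the literal diagonal)
follow the standard regularized-DA convention (Friedman-style shrinkage
toward a scaled identity rather than toward the literal diagonal; the
literal-diagonal variant differs only in the γ target). λ = 1, γ = 0 recovers LDA
(verified against an independent LDA implementation in the tests), λ = γ = 0
recovers QDA, which is typically infeasible here because class covariances
of 18 samples in ~10²-dimensional descriptor space are singular — exactly
the situation the default λ = 0.99, γ = 0.001 (nearly linear, minimal
diagonal loading) addresses. Priors default to uniform as the design is
balanced. A sample is assigned to the class minimizing

$$ds_k(x) = (x-\mu_k)^\top \Sigma_k^{-1} (x-\mu_k) + \ln\det\Sigma_k
- 2\ln\pi_k,$$

ties resolving to the lowest class index. `mahalanobis_distances()` and
`roc_auc_ovr()` (rank-formula AUC with midrank ties, using the negated
discriminant score) provide the descriptive diagnostics;
`rda_grid_search()` exposes the crude training-CRR sweep over a small
(λ, γ) grid.

### Cross-validation and the noise experiment

`make_stratified_folds()` builds 6 folds with exactly 3 test instances per
class (90 train / 18 test at the default design). The essential protocol
point is **per-fold re-selection**:
descriptor selection, standardization statistics and the RDA fit are
recomputed inside each fold from its training rows only, so no information
from any test row leaks into the classifier that judges it. A structural
test asserts that perturbing test rows changes neither the selected
descriptor set nor the standardization statistics. The reported figure is
the unweighted mean of the six per-fold correct recognition rates
(identical to the pooled rate here, as folds are equal-sized).

`add_shape_noise()` perturbs every matrix entry by uniform noise on
[-a·σ_j, +a·σ_j], where σ_j is the descriptor's standard deviation over the
full clean matrix and a is the amplitude. The σ referent is a genuine
design choice (per-descriptor vs global, before vs after standardization);
per-descriptor and pre-standardization were chosen so that an amplitude of
one standard deviation means the same thing for every descriptor regardless
of its scale, and the alternative is reachable by standardizing first.
Noise is applied to training and test rows alike before the whole protocol
reruns (`noise_experiment()`).

## The synthetic lesion generator

`generate_injury_dataset()` emulates a plasticine-model specimen set: 6 classes x
18 instances of an 8 mm square patch gridded 80 x 80 (about 10 vertices/mm,
nearly equilateral triangles), each deformed as a height field:

| class | deformation | key defaults (mm) |
|---|---|---|
| abrasion | band-limited random roughness in a soft elliptical footprint | amplitude 0.25, correlation length 0.8, footprint 2.6 |
| incised | straight V-groove, longer than deep | depth 0.9, half-width 0.35, length 5 |
| gunshot | flat-bottomed circular pit, steep walls, slight rim | depth 1.3, radius 0.9, rim 0.12 |
| smooth strangulation | wide transverse Gaussian groove | depth 0.7, width 1.2 |
| textured strangulation | the same groove + periodic stria | stria amplitude 0.04, period 1.0 |
| patterned | L-shaped sharp-walled indentation | depth 0.55, arm width 0.9, arms 3.2 / 2.2 |

Every instance draws jitter from its child seed: depth x U(0.45, 1.55),
width x U(0.55, 1.45), position ±1.5 mm, free rotation, plus class-specific
draws (groove length, stria period and phase, arm lengths, roughness
realization). The physical dimensions of the original plasticine lesions
are not available, so the absolute sizes above are plausible wound scales
chosen once; the jitter ranges are calibrated so the dataset reproduces the
intended *statistical regime* rather than any particular geometry: descriptive
training-set separation is essentially perfect (one-vs-rest AUC 1.0, the
regime the method reports) while within-class scatter is large enough that
the SNR filter does real work (a few hundred of 1284 descriptors at most
survive, instead of nearly all). Being height fields, the meshes cannot
self-intersect and keep exactly one vertex per grid node; true overhangs,
photorealistic texture and scanner artefacts beyond optional i.i.d. vertex
noise are out of scope.

What passing tests on these data do and do not show: they demonstrate that
the descriptor/selection/RDA machinery recovers class structure of the
intended kind from mesh geometry alone, at the design's sample sizes and
under its protocol. They do not certify performance on real scans, whose
noise structure (registration error, specular artefacts, clipping
variability) the generator deliberately does not model.

## Problem sizes and runtime

The end-to-end checks run the default design — 108 meshes of 6400 vertices,
1284 descriptors, 6 folds with per-fold selection — in roughly 30-50 s per
master seed on one core; the recognition-rate check uses three master
seeds and the noise experiment five (dataset, noise-draw) seed pairs at
amplitude 1 plus three at amplitude 10. These sizes match the full study
design (108 = 6 x 18, k = 6), so nothing is scaled down.

## Known limitations

* Plain triangle soups with inconsistent winding are rejected rather than
  repaired; mesh repair is out of scope.
* The curvature estimator assumes a locally smooth surface; on creases
  (V-groove apices, sharp pattern walls) it reports large finite values
  whose magnitude depends on grid resolution — acceptable here because all
  specimens share one resolution, but a caveat for mixed-resolution data.
* VRML 2.0, a format some structured-light scanners export, is not
  parsed; OBJ/PLY cover the same geometry content.
* The (λ, γ) grid search scores by training CRR — it is descriptive, not
  nested cross-validation, and should not be read as an unbiased
  parameter-selection procedure.
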