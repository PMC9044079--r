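---
title: "3D wheat grain phenotyping from surface point clouds: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{3D wheat grain phenotyping from surface point clouds: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grain3d)
```

## The measurement problem

Wheat grain dimensions (length, width, thickness), volume and surface area
are closely tied to single-grain weight and hence yield, while the ventral
sulcus — the longitudinal crease on the grain's ventral side — affects flour
extraction. Structured-light scanners produce dense merged surface point
clouds (coordinates in mm, sub-0.1 mm effective point spacing) of many
grains resting on a stage. grain3d turns such a scene into a table of 32
per-grain traits and a cross-validated single-grain weight model.

The pipeline is: voxel-grid downsampling, RANSAC removal of the stage
plane, statistical outlier removal, region-growing segmentation into single
grains, then per-grain measurement: PCA alignment, oriented-bounding-box
dimensions, surface reconstruction (area and enclosed volume), projections
along the three principal axes, and cross-section slicing for the sulcus
traits.

## Per-grain measurement model

**Alignment.** Each grain is centred at its centroid `A` and rotated by the
eigenvector matrix of its covariance, `T_A = M (T0 - A)`, so x carries the
largest variance (the grain length axis) and z the smallest. Eigenvector
sign is fixed by making each of the first two eigenvectors' largest
components positive; the third axis is their cross product. (Fixing all
three signs independently can produce a reflection, so right-handedness
wins for the third axis.)

**Dimensions.** In the aligned frame the oriented bounding box is the
axis-aligned box: `l = x_max - x_min`, `w = y_max - y_min`,
`h = z_max - z_min`.

**Surface and volume.** The grain surface is reconstructed as a triangle
mesh whose vertices are input points, by *radial Delaunay triangulation*:
points are mapped to unit directions about the centroid, triangulated on
the sphere (stereographic projection from one of the data points, planar
Delaunay, closure of the projection cap — together equivalent to the convex
hull of the directions), and the connectivity is pulled back to the
original coordinates. For a closed, star-shaped surface sample — which a
merged scan of a wheat grain is, crease included — this mesh is watertight
by construction. We chose this over incremental greedy-projection meshing
because it guarantees a closed mesh without hole-repair heuristics, has no
search-radius tuning, and keeps the "mesh vertices are measured points"
property; its limitation (strongly non-star-shaped cavities would fold) is
immaterial for grain-shaped objects. Surface area is the sum of
per-triangle Heron areas (side lengths `a_i, b_i, c_i`, semi-perimeter
`p_i`, `s_i = sqrt(p_i (p_i - a_i)(p_i - b_i)(p_i - c_i))`), identical to
the cross-product form to rounding; degenerate radicands clamp to zero.
Volume is the signed-tetrahedron sum about the centroid after consistency
checks (every edge on exactly two faces; boundary loops of at most 30 edges
are fan-filled, larger holes are an error; orientation is propagated and the
global sign fixed) — algebraically the same as summing per-face prisms over
a central plane for a closed oriented mesh.

**Projections.** The aligned grain is projected along each axis; the planar
points are Delaunay-triangulated and triangles with any side longer than a
cut (default 2.5 x the 90th-percentile Delaunay edge scale) are discarded, so
concavities such as the crease mouth are respected. Area is the sum of kept
triangles; perimeter the sum of edges used by exactly one kept triangle.
Roundness is `c = 4*pi*S0 / C^2` per section; sphericity
`E = pi^(1/3) (6V)^(2/3) / S_a`.

**Sulcus traits.** Nine slabs perpendicular to the length axis, 0.4 mm
apart and centred on the grain centre, are projected to (y, z) profiles,
and the profile with the largest convex-hull area is measured. The slab
thickness default is 0.4 mm: at a merged-scan density of roughly 40-150
points/mm^2 this yields on the order of a hundred points per slab, enough
for a stable hull; thinner slabs starve the profile. The crease lips are
found as the endpoints of the hull edge bridging the profile's deepest
concavity (its deepest "pocket"), the deepest point is the pocket point
nearest the centre of a RANSAC-fitted circle (all slice points feed the
fit; if no consensus circle exists, the point furthest from the lip chord
is used — the two coincide for a clean groove), and the depth `D` is the
mean chord distance of the few (up to five) deepest pocket points: the
crease is a ridge along the grain axis, so the slab contains several points
of essentially equal true depth, and averaging them suppresses single-point
scan noise without eroding the fold. Two degenerate profile classes are handled
explicitly: a convex profile has no pocket and reports a depth near zero,
with the hull-diameter pair standing in as edge points; an open crescent
profile (all points on one side of the hull diameter, as when only part of
a section is visible) measures its sagitta from the diameter chord. A
profile whose lip chord is far from perpendicular to the groove direction
is flagged with a warning, since the edge-point rule is ambiguous there.
Slice perimeter reorders the slab points by polar angle about their
centroid and sums adjacent distances; slice area is the centroid-fan
(shoelace) area, so concave groove walls subtract correctly; sulcus area is
the convex-hull area minus the slice area. Star-shapedness about the
centroid is assumed and violations only warn.

**Why the deepest pocket and not the two furthest hull points.** On any
closed cross-section the two mutually furthest hull vertices span the
section's width, a chord that sits half a thickness away from the crease;
depth measured from it would equal thickness minus crease offset and would
not vanish for a creaseless grain. The pocket construction returns the
groove lips whenever a groove exists, degrades gracefully to the diameter
pair when it does not, and is what the manual protocol (deepest crease
point to the line through the two crease edge points) actually measures.

## Noise handling: two measurement paths

Scanner noise enters the extent measurements through extreme-value
statistics: `x_max` of thousands of noisy samples sits a few noise sigmas
above the true surface, biasing `l`, `w`, `h` upward. The pipeline
therefore applies moving-least-squares smoothing (projection of each point
onto the least-squares plane of its 8 nearest neighbours) before the
bounding box, mesh and projection measurements. The same projection,
however, erodes sharp concave features — it planes off the crease fold and
biases depth low — so slicing and all sulcus traits use the unsmoothed
(only voxel-downsampled) points. Splitting the paths by trait class
resolves a genuine conflict: no single smoothing level serves both an
extreme-value statistic and a sharp-feature measurement.

Voxel downsampling uses half-open cubes anchored at the global coordinate
origin rather than at the cloud's minimum corner: a centroid then never
leaves its voxel, making the operation exactly idempotent, whereas a
min-corner anchor shifts the grid after the first pass and can merge
centroids.

## Scene processing defaults

| knob | default | why |
|---|---|---|
| `voxel_size_mm` | 0.1 | just under the scanner's 0.16 mm point distance; merged multi-view clouds are denser, so this pools 1-3 points per voxel |
| `outlier_k`, `outlier_std_ratio` | 20, 2.0 | standard statistical outlier removal scale |
| `ransac_threshold_mm` | 0.15 | ~3 sigma of stage roughness + scan noise |
| `ransac_iterations`, `ransac_seed` | 1000, 0 | >99.9% hit probability for a half-inlier plane; fixed seed for determinism |
| `rg_k`, `rg_angle_deg`, `rg_curvature` | 30, 12, 1.0 | region growing over k-NN links; 12 degrees tolerates scan noise on a smooth grain but not the jump between grains |
| `cluster_min`, `cluster_max` | 200, 20000 | the primary user knob: a grain at working densities falls well inside; debris and merged blobs fall outside |
| `n_slices`, `slice_interval_mm`, `slab_thickness_mm` | 9, 0.4, 0.4 | nine sections at 0.4 mm mirror the manual sectioning protocol; slabs tile the grain |
| `circle_threshold_mm`, `circle_iterations` | 0.05, 500 | sub-noise band for the section circle fit |

Region growing compares neighbour normals by absolute dot product, so no
global normal orientation step is needed; grains in contact are not split
further (a documented limitation — no watershed step is attempted).

## The synthetic generator

`make_grain()` emulates a merged structured-light scan of one grain with
exact ground truth. The body is a superellipsoid (exponent 2 by default,
i.e. an ellipsoid) with semi-axes a >= b >= c, default 4 x 1.6 x 1.4 mm —
an 8 mm grain in the 6-10 mm class. The crease is carved per cross-section:
the elliptical arc between two lip points (`groove_width` = 1.2 mm apart on
the ventral side) is replaced by a V-fold whose tip sits exactly
`groove_depth` (default 0.5 mm, sub-millimetre like the real sulcus) above
the lip chord, tapering smoothly to nothing beyond 90% of the half-length.
This construction makes the planted depth *by definition* the chord-to-tip
distance that the sulcus measurement estimates; a generator whose "depth"
parameter is not the measured geometric quantity cannot serve as ground
truth. Sampling is area-weighted on the deformed surface by rejection
sampling against the numerically evaluated area element (no pole
clustering), plus isotropic Gaussian noise (default sd 0.02 mm, a
merged-cloud residual under the scanner's 0.05 mm single-shot accuracy).
The default 12,000 points correspond to a merged multi-view cloud at
~0.08 mm effective spacing — denser than the 0.16 mm single-view point
distance, which is what makes the 0.1 mm voxel pass meaningful.
Ground-truth `l`, `w`, `D` are analytic; `h`, `V`, `S_a` and the
central-slice measures come from fine-grid quadrature of the same
parameterisation (verified against Monte-Carlo integration in the tests).

What the generator does **not** emulate: view-dependent occlusion and
merging artefacts, specular dropouts, spatially correlated (low-frequency)
calibration error, stage-colour and angle effects, and grain-to-grain
contact. Passing the synthetic recovery suite therefore demonstrates the
geometry chain is correct under realistic density and iid noise, not that
every scanner artefact is survivable.

`make_scene()` lays randomized grains (length 6.4-8.4 mm, depth 0.3-0.7 mm)
crease-up on a 12 mm grid above a sampled stage plane with per-point truth
labels; grains rest on the stage, so the stage-removal step genuinely cuts
their lowest points, as on a real scan. `make_weight_dataset()` measures
each generated grain with the real trait pipeline and plants
`weight = 1.2 mg/mm^3 * V + N(0, 0.5 mg)` on the *measured* volume (so a
noiseless table is exactly linear); the defaults land in the realistic
25-50 mg single-grain range.

## Trait table, evaluation metrics, and the weight model

The 32 traits (16 basic, 16 derived) follow the standard naming: `l, w, h,
V, S, D`, section perimeters/areas `C_yz, S_yz, C_xz, S_xz, C_xy, S_xy`,
slice measures `C_c, S_c, S_s`, the ratios, box volume `V_obb = l*w*h`,
specific surface `S/V`, roundness per section and sphericity `E`.

Agreement metrics are MAPE (reported in percent), RMSE, and
`R2 = 1 - sum((x_i - y_i)^2) / sum((x_i - ybar)^2)` where x are reference
and y system values and — deliberately — `ybar` is the mean of the *system*
values. That convention is kept as the package default for comparability;
`r2_baseline = "reference"` switches to the textbook definition (the two
coincide when predictions are unbiased).

The Taguchi L9 range analysis computes `K[f, i]` as the **mean** response
of the three tests at level i of factor f and `R[f]` as the range of K.
(The bundled scan-condition table's footnote describes K as a sum, but its
printed K values are means; the level-3 rotation entry as printed, 0.0731,
is also inconsistent with its own three responses, whose mean is 0.0743 —
the analysis reports the recomputed value.) Best levels minimise K, giving
black stage, 30 degree rotation, 37 degree scanning for the bundled table.

`train_weight_models()` evaluates LR, Bayesian ridge, KNN, random forest
and gradient boosting by k-fold cross-validation (default 10): features are
standardised on each training fold only, and hyperparameters (KNN k in
{3,5,7,9,11}; RF trees {100,300,500} x depth {unlimited,5,10}; GBR learning
rate {0.05,0.1} x trees {100,300} x depth {2,3}) are chosen by grid search
nested inside each training fold, so no test-fold information leaks into
model selection. Reported metrics are per-fold means computed with the same
`metrics()` implementation as everything else. The Bayesian ridge is the
standard evidence-approximation (type-II maximum likelihood) estimator,
implemented in-package and cross-checked against least squares on clean
data. All randomness flows from one seed; tree learners run single-threaded
for reproducibility.

## Problem sizes used in the validation suite

The bundled tests and the acceptance script run entirely on synthetic data:
parameter recovery uses 50 random grains at the default 12,000 points;
segmentation uses one 25-grain tray (~60,000 scene points); the weight
harness uses 500 grains generated at 1,200 points each (the dimensional
traits that carry the weight signal are stable at that density, and a
500-grain batch stays tractable); unit fixtures are smaller. These sizes
are the package's validation choices and match the scales the method is
designed for (trays of 25 grains, 500-grain experiments).

## Known limitations

- Touching grains are returned as one segment; the region-growing knobs can
  reject (not split) them.
- Slice perimeter and hull-derived sulcus area inflate with point noise
  (zigzag and hull-envelope effects, roughly noise x perimeter); depth and
  the dimensional traits are robust to this, which mirrors the larger
  errors slice-level traits show in practice.
- The edge-point rule for the sulcus is ambiguous for sections taller than
  wide; such profiles are flagged with a warning rather than silently
  measured.
- The radial triangulation assumes a star-shaped grain; deeply folded
  surfaces (not wheat-like) would need a local meshing method.

## A minimal session

```{r example, eval = FALSE}
set.seed(1)
scene <- make_scene(n_grains = 25, seed = 1)
res <- run_pipeline(scene$cloud, output_dir = "out/")
res$traits

doe <- run_doe(system.file("extdata", "l9_scan_conditions.csv",
                           package = "grain3d"))
doe

tab <- make_weight_dataset(n = 500, seed = 1)
report <- train_weight_models(tab, folds = 10, seed = 0)
tidy(report)
autoplot(report)
```
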