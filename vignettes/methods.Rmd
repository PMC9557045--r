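---
title: "Methods: silhouette-based knee implant size prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: silhouette-based knee implant size prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tkrsize)
```

`tkrsize` predicts total-knee-replacement component sizes from two
orthogonal knee silhouettes. This vignette documents the model choices,
the tunable parameters, the synthetic data the package is validated on,
and the known limitations — in that order of importance for anyone
adapting the package to new data.

## Coordinate convention

All 3D geometry lives in a canonical right-knee frame: X runs medial to
lateral (+X lateral), Y posterior to anterior (+Y anterior), Z distal to
proximal. Left knees are mirrored about the YZ plane on ingest
(`mirror_mesh()`, or the AP-mask flip inside `mask_to_contour()`), so all
downstream code sees right knees. Within that frame the pipeline is
deliberately insensitive to residual rigid motion: the medial half is
taken relative to the bounding-box centre, the resection plane is built
from the bone's own plateau orientation, and all component registrations
are ICP-based.

## The two fit metrics

Both metrics are computed between an implant component held at its fitted
pose and the bone.

* **Global RMSE.** For `N` points sampled area-uniformly on the component
  surface, the root mean square of each point's Euclidean distance to its
  closest point on the bone surface. Closest points are exact
  point-to-*triangle* feet (a point-to-vertex shortcut would bias the
  error upward by a tessellation-dependent amount, which matters because
  typical values are ~1 mm). A compiled kernel with a bounding-sphere
  prune makes the exhaustive query cheap; unit tests pin it against a
  feature-enumeration oracle to 1e-9.
* **Maximum over/underhang (OUH).** The directed Hausdorff distance from
  component edges to bone edges: the worst protrusion of the implant
  boundary beyond the bone, or the worst uncovered bone span, both
  reported as positive distances. The metric is *directed* — distances
  are measured from the component — and edges are resampled to at most
  0.2 mm spacing before evaluation so that discretization contributes at
  least an order of magnitude less than the 3 mm clinical threshold.

## Virtual implantation

**Tibia.** The resection plane is parallel to the medial plateau surface
and passes 2 mm (along the plateau normal) below the widest point of the
medial condyle. Operationally: upward-facing vertices (normal Z
component > 0.8) on the medial half are collected; vertices within 35% of
the half-width of the midline are dropped (they sit on the intercondylar
eminence, not the plateau facet); a least-squares plane with one guarded
outlier-trim pass gives the normal; the widest point is the most medial
vertex. The plate's 2D profile is registered onto the resection
cross-section by 3-DOF in-plane ICP — rotation only about the plate's
central axis, no flexion/extension, mirroring how a surgeon may rotate
but not tilt the plate. RMSE uses the full plate profile; OUH uses the
fit-analysis edge contour, in which the posterior stabilizing notch is
excluded (closed by the profile's smooth un-notched continuation). A
straight chord across the notch was considered and rejected: even at a
perfect size match a chord sits ~1 mm off the bone boundary and that
constant artefact would leak into every OUH value.

**Femur.** The component's articular surface samples are registered to
the bone by unconstrained 6-DOF ICP, initialized by translating the
component onto the distal-femur centroid with axes aligned (only the
tibia's rotation is constrained; the femoral component seats on oblique
cuts and needs all six degrees of freedom). RMSE uses all surface
samples. OUH compares the component's peripheral rim — the
maximal-extent ring where the implant border meets the resected bone —
with the bone's cross-section at the rim's level, both projected into the
rim plane. The distal cut is held perpendicular to the component's Z
axis (no flexion of the distal resection).

**Selection.** Every size of every chart is fitted; per chart and metric
the size with the lowest error is reported. If a smaller size is within
`downsize_tiebreak_tol` (default 0.05 mm, configurable) of the minimum,
the smaller size wins — when the fit difference is within measurement
error, downsizing is the clinically safer call. Chart order (the printed
size progression) defines the ordinal used for this tie-break and for
±1-size accuracy; size labels are not arithmetic (Stryker femur sizes
run ... 9, 11, 13).

## 2D→3D reconstruction

Masks are an input contract: any upstream segmenter that produces one
clean foreground component per view can feed the pipeline (an Otsu
threshold fallback is included for synthetic grayscale projections; CNN
segmentation is out of scope here). Contours are traced from the largest
foreground component and offset outward by half a pixel so the polygon
area matches the foreground area.

The two views are aligned by (a) centring each horizontally, (b)
uniformly scaling the lateral contour so both views share one vertical
extent — radiographic magnification differs between views and absolute
scale is owned by the AP view — and (c) matching a shared anatomical
datum vertically: the most distal point for femora, the most proximal for
tibiae. Views whose vertical extents disagree by more than 25% are
rejected as inconsistent.

Each aligned contour is resampled to `P = 200` arc-length-uniform points
starting from the datum point (ties broken toward the larger first
coordinate). The **point depth model** assigns each contour point the
mean out-of-plane coordinate of the corresponding silhouette-generator
point across training bones, scaled by the contour's vertical extent
relative to the training mean. PCA modes of the depth residuals are
retained in the container for future refinement but the current estimator
uses the scaled mean profile — the simplest model that turns a contour
into a 3D reference curve.

The **statistical shape model** is built from correspondent point clouds
(template ICP + closest-point projection), aligned by generalized
Procrustes analysis with similarity transforms (uniform scale included,
because silhouette magnification makes absolute scale uncertain), and
decomposed by PCA. Fitting alternates two exact least-squares steps:
similarity alignment of the current instance to the reference points,
and a linear solve for the mode coefficients with each coefficient
clamped to ±3 standard deviations of its mode. Both steps decrease the
matched objective, so the iteration is monotone under its
closest-point correspondence; it stops when the objective changes by
less than 1e-4 mm (default cap 60 iterations, with a warning flag on
non-convergence — in the benchmark this occurs occasionally and
harmlessly, the remaining change being far below the reconstruction
error).

## Synthetic data: what it emulates, what it does not

`generate_bone()` builds parametric bones: the femur is a star-shaped
condylar surface (two condyles, trochlear/intercondylar groove, narrowed
and elongated shaft stub); the tibia is an extruded kidney profile with a
flat medial/lateral plateau, a central intercondylar eminence (2.5 mm),
a metaphyseal flare whose widest ring sits 5 mm below the articular rim,
and a shaft taper. Dimensions are exact: after shape deformation the
mesh is affinely rescaled so the ML/AP extents equal the request to
within 0.1 mm, with the Z scale tied to the mean of the X and Y factors.

Shape variability comes from a fixed 4-mode smooth displacement basis
(axial bulge, two axial skews, ML-AP coupling; orthonormalized, 1 mm RMS
per unit coefficient) — fixed so that model-training tests can check
recovery of a *known* spectrum. Surface noise is a smooth correlated
field (sum of random plane waves, 20–40 mm wavelengths, marginally
~N(0, sd²)) applied along vertex normals: segmentation error on real
bone is spatially smooth, and white per-vertex jitter would both inflate
bounding extents and let single vertices dominate the max-based OUH
metric.

`generate_population()` draws cohorts with sex-conditional dimension
distributions chosen to span the packaged chart ranges (female/male femur
ML means 62/70 mm, tibia 66/74 mm, sd 3.2 mm; AP regressed on ML with
ratio 0.88 for femora and 0.655 for tibiae and 1 mm residual sd — the
"dimension noise" of the benchmark), ages uniform on 46–79, random side,
and per-subject surface noise of 0.3 mm (typical MRI-segmentation error;
training sets use 0.2 mm). These are the package's fixed study
conditions, not tuning knobs.

What passing tests on this generator shows: the geometry engine, the
metrics, the resection construction, the reconstruction machinery and
the selection logic are correct and stable at realistic error
magnitudes, and the end-to-end tool tracks the ground-truth best size to
within one size almost always. What it does not show: performance on
real radiographs — real bones have condylar asymmetries, osteophytes and
segmentation failure modes outside this shape family, and the SSM here
is trained on the same family it reconstructs, which flatters
reconstruction accuracy relative to a clinical setting.

## Benchmark problem sizes and numerical choices

The checked-in benchmark uses 60 training bones (20 for the depth
models; the published counts for the clinical analogue are 100 and 20),
a 50-subject test cohort, bone meshes of ~650–760 vertices, 2000+
component surface samples (200 subsampled for ICP correspondences), and
0.5 mm/px masks. Tolerances: ICP stops at 1e-4 mm objective change
(25 iterations femur-side); Hausdorff densification 0.2 mm; downsize
tie-break 0.05 mm; plateau identification needs 50 upward medial
vertices. Degenerate inputs fail loudly: zero-area target faces are
skipped (all-degenerate errors), collinear ICP sources are rejected,
planes that miss a mesh or cut only open chains raise errors, and a
rotationally symmetric contour resolves its unidentifiable rotation to
zero by the least-squares tie-break.

## Known limitations

* The tibial resection depth rule (2 mm below the widest medial point)
  assumes the plateau is identifiable and roughly perpendicular to the
  shaft; severe deformity or a plateau slope relative to the shaft axis
  would need the surgeon-set resection the rule intentionally sidesteps.
* The femoral OUH is evaluated at the peripheral rim against the matching
  bone section; flange-tip overhang proximal to the rim plane is not
  separately scored.
* Generic templates stand in for proprietary implant geometries, so
  absolute fit values are not manufacturer claims; only the relative,
  per-chart comparisons are meaningful.
* Reported accuracies are on the synthetic family (see above), not on
  clinical data.
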