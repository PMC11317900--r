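---
title: "Estimating floret contact points from radially resliced CT volumes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating floret contact points from radially resliced CT volumes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(capitulum3d)
```

## The estimation problem

A capitulum packs many florets onto a rotationally symmetric receptacle.
The 3D coordinates of the floret–receptacle contact points describe the
phyllotaxis of the head, but they cannot be read directly from a CT volume:
contact points are small features that are only detectable on 2D section
images, and each physical contact point appears on several sections. The
pipeline in this package turns per-section 2D detections into a single set
of 3D estimates, and quantifies every error source along the way.

The stages, and the assumptions each one rests on, are:

1. **Axis alignment** (`rotate_volume_to_axis`). The method assumes the bud
   is (approximately) a body of revolution and that its rotation axis is
   known — in practice supplied by visual inspection. The volume is
   resampled by nearest neighbour so that this axis becomes the z grid
   axis; voxels whose preimage falls outside the source grid take the mean
   source intensity, so the filled border does not shift the intensity
   statistics that a downstream detector sees.
2. **Radial reslicing** (`slice_at_angle`, `generate_slices`). Sections are
   sampled in planes *containing* the axis, at azimuths θ = 0, Δθ, …,
   180° − Δθ. A plane carries a signed radius r = h − (width−1)/2, so each
   image spans the full bud diameter and 180° of planes cover the whole
   revolution (3600 images at Δθ = 0.05°). Slicing this way, rather than
   perpendicular to the axis, makes all sections look alike — a cone
   flanked by florets — which is what lets one 2D detector generalise
   across the whole volume.
3. **Detection and segmentation** are external: the package consumes ranked
   bounding boxes and binary receptacle masks per slice, and evaluates them
   with IoU, COCO AP and Dice (`iou`, `ap_suite`, `dice`).
4. **False-positive gating** (`filter_detections`). Many image regions
   resemble contact points; true ones lie on the receptacle. A detection is
   kept iff at least one mask-true pixel centre falls inside its half-open
   box. No area threshold is applied: the prior is binary
   (on-receptacle / off-receptacle), and the overlap rule is deliberately
   the weakest one consistent with it, so the gate never discards a
   borderline true detection that merely grazes the mask.
5. **Integration and clustering** (`backproject_detections`,
   `agglomerate`). Box centres are mapped to voxel coordinates through
   their plane's geometry. The resulting cloud contains one clump of points
   per contact point; group-average agglomeration merges while the smallest
   inter-cluster group average is < d and stops at ≥ d, and cluster
   centroids are the estimates. Hierarchical clustering is used precisely
   because the number of contact points is unknown: the threshold d, not a
   preset cluster count, decides the partition.

## The clustering criterion and its threshold

Group average,
$$d(A,B) = \frac{1}{|A||B|}\sum_{x \in A}\sum_{y \in B} \lVert x-y\rVert,$$
is preferred over single or complete linkage here because the point clumps
are elongated (they trace short arcs across adjacent slices): single
linkage chains neighbouring clumps together near the apex, while group
average requires the *bulk* of two clumps to be close before merging.

`agglomerate` maintains inter-cluster distances with the average-linkage
Lance–Williams recurrence
$d(A{\cup}B, C) = (|A|\,d(A,C) + |B|\,d(B,C))/(|A|+|B|)$, which is exact
for this criterion; correctness is defined by (and tested against) a naive
oracle that recomputes all pairwise cluster means from scratch each
iteration, and cross-checked against cutting `stats::hclust(method =
"average")` dendrograms at height d. Ties on the minimal distance are
broken deterministically towards the lexicographically smallest
(older, newer) pair of cluster-creation indices; ties are measure-zero for
continuous data but the rule makes replicated runs bit-identical.

The termination comparison is *merge while min < d, stop at ≥ d*. Two
points exactly d apart therefore do **not** merge. The threshold has the
units of voxels and its useful range is set by the data: d must exceed the
within-clump scatter (tangential spacing + 3σ of detection jitter) and stay
below the floret spacing. On real data d is chosen by inspecting the
cluster count and colouring over a sweep (the package emits the
count-versus-d table for exactly this purpose); `simulate_pipeline`
defaults to half the minimum ground-truth nearest-neighbour distance, the
midpoint of that admissible interval.

## Error structure of the reslicing geometry

Within a slice (radial direction), detector error is mitigated by
averaging: a contact point seen on N slices contributes N jittered
positions whose centroid error shrinks as the zero-mean jitter averages
out. The suite asserts this empirically (centroid error at N = 100
supporting slices is below that at N = 5 over 200 replicates).

Across slices (tangential direction), the error is geometric: adjacent
planes are `r` · Δθ_rad apart at radius r, so the worst-case displacement
of a point at the volume edge is width/(90/Δθ) pixels
(`max_tangential_error`). For the reference geometry — 2048 px width,
Δθ = 0.05°, 2.75 µm voxels — that is 1800 planes per quadrant and
2048/1800 ≈ 1.14 px ≈ 3.13 µm. Contact points sit well inside the edge, so
their tangential error is proportionally smaller.

Near the axis the geometry reverses: sampling is densest there, but the
florets are also densest (apex of the cone), so clustering, not sampling,
limits accuracy — clumps of neighbouring apical florets overlap at any
single global d. This is why positional error *increases* towards the axis
even though plane spacing decreases, and why the evaluation reports each
estimate's distance from the axis alongside its error. An adaptive,
radius-dependent d would address it but is out of scope.

## Detection metrics

AP follows the COCO convention: detections ranked by confidence (pooled
across slices; ties keep input order), greedily matched to the unmatched
same-slice ground truth of highest IoU, counted correct iff IoU is
*strictly greater* than the threshold, and the precision envelope is
averaged at the 101 recall points 0.00, 0.01, …, 1.00. The strict
inequality and the 101-point grid are the two conventions a reimplementer
must pin down; both are asserted by enumeration oracles in the tests
(e.g. ranked labels TP, FP, TP with two ground truths give
(51 + 50·⅔)/101 ≈ 0.835, and detections at uniform IoU 0.6 give
AP(0.5:0.95) = 2/10, since only the 0.50 and 0.55 thresholds pass a strict
comparison). Boxes are half-open continuous rectangles, which makes the
closed-form IoU equal the rasterised pixel-set IoU for integer-aligned
boxes — also asserted on random boxes. Dice relates to IoU by
DSC = 2·IoU/(1+IoU); the identity is asserted on random masks.

## What the synthetic bud does and does not emulate

`bud_spec`/`make_bud` place n florets on a surface of revolution — cone
z = z_apex − r/tan(α) or paraboloid z = z_apex − r²/c — along a Vogel
spiral: point k (k = 0 at the apex) at azimuth k·137.508° and radius
c·√k. This reproduces the two properties the pipeline is sensitive to:
apex-dense packing and roughly uniform area coverage. It is *not* a
mechanistic phyllotaxis model, and no claim about real floret arrangement
rests on it.

`simulate_detections` models the detector as: a contact point is visible on
a slice iff its perpendicular distance to the plane is ≤
`capture_halfwidth_px` (the stand-in for the physical extent that makes a
point appear on multiple slices; default 3 px, chosen to exceed half the
worst tangential spacing at the default geometry so every floret is covered
by at least one plane); visible points are emitted with probability
1 − p_miss at their in-plane projection plus isotropic Gaussian jitter;
Poisson(fp_rate) false positives per slice are placed with their whole box
off the receptacle mask, so the filter's effect is measurable in isolation
(removal and retention rates are exact percentages, not estimates). With
all noise zero the simulator reduces to the idealised setting in which
detection and outlier removal are assumed perfect, isolating the error
contributed by reslicing + integration + clustering alone.

Not emulated: X-ray photometry and reconstruction artefacts, floret/
involucre anatomy, non-axisymmetric receptacles, detector confidence
calibration (confidences are drawn uniformly), and spatially correlated
detector failures. Passing tests therefore validate the *geometry and
statistics* of the pipeline, not any claim about a particular detector's
accuracy on real CT images.

## Reference experiment and problem sizes

The package's standing accuracy experiment uses a 90-floret conical bud of
radius 400 px (apex at z = 500, half-apex angle 45°), noiseless detections,
0.5° slicing — 360 planes, ~650 back-projected detections. These sizes keep
every property assertable while preserving the regime that matters: floret
spacing (≈ 60 px minimum) an order of magnitude above the within-clump
scatter (≤ ~3.5 px). Under these conditions the pipeline recovers exactly
90 clusters for every d in a broad plateau (10–50), with mean positional
error ≈ 0.5 px and mean nearest-floret-distance error < 1 px for florets
more than 20 px from the axis — the same sub-pixel spacing accuracy the
error analysis above predicts for non-apical florets. `scripts/acceptance.R`
recomputes all of these from scratch.

## Numerical choices and degenerate inputs

- Coordinates are 0-based with pixel/voxel centres at integers; the
  rotation/slicing centre is the continuous grid centre ((N−1)/2 per axis),
  symmetric for odd and even dimensions.
- Nearest-neighbour ties round half away from zero, everywhere, so slices
  and rotations are reproducible across platforms.
- All computation stays in voxel units; µm appear only at reporting time
  (voxels are isotropic).
- The out-of-bounds fill value is computed once per volume over all voxels,
  not per slice.
- Degenerate inputs error early: empty point sets, zero-area boxes, two
  empty masks in a Dice, non-divisor slicing intervals, axis directions
  that are zero or antiparallel to z (the antiparallel case is rejected
  rather than silently picking one of the two valid 180° rotations).
- The summary standard deviation of positional errors is the population
  (divide-by-n) form.
- Multiple detections per slice are *not* deduplicated before integration;
  clustering absorbs duplicates by design.
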