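# capitulum3d

Estimating the 3D positions of floret–receptacle contact points in micro-CT
volumes of rotationally symmetric flower buds.

## The problem

A composite flower head (a capitulum, as in chrysanthemum or sunflower)
carries tens to hundreds of florets on a common receptacle. The point where
each floret meets the receptacle — the *contact point* — encodes the
phyllotactic arrangement of the head, and micro-CT makes it observable
non-destructively. But a CT volume of a bud is far too large to annotate by
hand, and contact points are small, low-contrast features that an object
detector can only find reliably in 2D section images.

`capitulum3d` implements the geometry and statistics around such a 2D
detector:

1. **Radial reslicing.** After the bud's rotation axis is aligned with the
   volume z-axis, mid-longitudinal sections are sampled at a fixed angular
   increment Δθ. Pixel (h, v) of the slice at azimuth θ maps to the world
   point (cx + r·cos θ, cy + r·sin θ, v) with signed radius
   r = h − (width−1)/2, so planes at θ ∈ [0°, 180°) cover the whole
   revolution and every slice has a similar appearance — which is what makes
   a single 2D detector applicable to all of them. Because adjacent planes
   diverge with distance from the axis, a point at the volume edge can fall
   up to `width / (90/Δθ)` pixels from its nearest plane
   (`max_tangential_error()`): for a 2048-px volume at Δθ = 0.05° that is
   2048/1800 ≈ 1.14 px, i.e. ≈ 3.13 µm at 2.75 µm/voxel.
2. **Detection evaluation.** Standard detector metrics over ranked
   detections: IoU(P, G) = |P∩G|/|P∪G|, COCO-style average precision with
   101-point interpolation (AP50, AP75, AP(0.5:0.95)), and the Dice
   coefficient DSC(P, G) = 2|P∩G|/(|P|+|G|) for receptacle segmentation.
3. **False-positive removal.** Contact points exist only on the receptacle,
   so any detection whose bounding box does not overlap the segmented
   receptacle region is discarded (`filter_detections()`).
4. **3D integration and clustering.** Each kept detection's box centre is
   back-projected through its slice plane into voxel coordinates. Because a
   contact point has physical extent, it appears on several adjacent slices;
   the resulting point cloud is grouped by group-average (UPGMA)
   agglomerative clustering, d(A,B) = (1/|A||B|) Σ_{x∈A} Σ_{y∈B} ‖x−y‖,
   merging while the smallest inter-cluster distance is below a threshold d
   and stopping at ≥ d. Cluster centroids are the contact-point estimates;
   averaging N noisy per-slice positions cancels zero-mean detection error.
5. **Synthetic buds.** A parametric simulator (conical or paraboloid
   receptacle, golden-angle Vogel-spiral floret placement, per-slice
   detection jitter/misses/false positives) exercises every stage without
   any CT data and provides ground truth for accuracy experiments.

Detector and segmenter training/inference are out of scope: the package
consumes their per-slice outputs (CSV boxes + confidence, TIFF masks) or
simulates them.

## Worked example

Simulate a 90-floret bud with a conical receptacle of radius 400 px, slice
at 0.5°, emit noiseless detections, filter, integrate and cluster:

```r
library(capitulum3d)

spec <- bud_spec(n_florets = 90, receptacle = "cone",
                 base_radius = 400, apex_z = 500, seed = 1)
sim <- simulate_pipeline(spec, interval_deg = 0.5)
sim$contact_points
#> <contact_points> 90 contact points estimated from 645 detections (d = 29.8142)

ev <- evaluate_positions(sim$contact_points, sim$gt_points,
                         axis_xy = spec$center_xy)
ev
#> <contact_eval> 90 estimates: error mean 0.5242, sd 0.3984 (voxels)

sweep_cluster_counts(sim$points, c(1, 10, 20, 30, 40, 50))
#>    d n_clusters
#> 1  1        252
#> 2 10         90
#> 3 20         90
#> 4 30         90
#> 5 40         90
#> 6 50         90
```

The 645 per-slice detections collapse to exactly the 90 planted contact
points (once d exceeds the within-cluster scatter), with a mean positional
error of ~0.5 px — well under the 1.14 px worst-case tangential spacing of
the slicing itself. At d = 1 the scatter is over-segmented into 252
clusters, the same over-/under-segmentation behaviour the threshold sweep
is designed to expose on real data.

```r
e <- max_tangential_error(2048, 0.05, voxel_size_um = 2.75)
#> 1800 slices per quadrant; worst-case tangential error 1.14 px = 3.13 um
```

A command-line interface wrapping the same functions is installed at
`inst/cli/capitulum3d.R` (subcommands `simulate`, `align`, `slice`,
`filter`, `integrate`, `cluster`, `sweep`, `evaluate`, `run`).

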