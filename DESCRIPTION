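Package: capitulum3d
Title: 3D Contact-Point Estimation in Rotationally Symmetric Flower-Bud CT Volumes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for localising floret-receptacle contact points in micro-CT
    volumes of rotationally symmetric flower buds (e.g. Asteraceae capitula).
    Provides radial mid-longitudinal reslicing of axis-aligned volumes with
    exact plane-to-world coordinate transforms and a worst-case tangential
    error bound; COCO-style object-detection evaluation (IoU, AP50/AP75/
    AP(0.5:0.95)) and Dice segmentation scoring; segmentation-gated removal of
    false-positive detections; back-projection of per-slice detections into a
    3D point cloud and group-average (UPGMA) agglomerative clustering with a
    distance-threshold termination rule, whose cluster centroids are the
    contact-point estimates; and a parametric synthetic-bud simulator
    (surface-of-revolution receptacle, golden-angle phyllotaxis, detection
    noise) so every pipeline stage can be exercised and validated without
    original CT data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    tiff,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
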