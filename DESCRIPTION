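Package: tkrsize
Title: Automatic Total Knee Replacement Implant Size Prediction from
    Bi-Planar Silhouettes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs 3D distal-femur and proximal-tibia surfaces from
    bi-planar (AP + lateral) silhouette contours using statistical shape
    models and per-view point depth models, virtually fits every size of
    five commercial knee-implant size charts to the reconstruction, scores
    each fit by global root-mean-squared surface error and by maximum
    over/underhang (directed Hausdorff distance between component and bone
    edges), and reports the best size per metric. Includes a synthetic
    bone generator and silhouette projector so the whole pipeline runs and
    is testable without any clinical data, plus evaluation utilities for
    ground-truth-best size accuracy analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    png,
    EBImage,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
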