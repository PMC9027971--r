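Package: kneeplanr
Title: Multi-Stage 2D Surgical Planning for Knee Ligament Reconstruction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A multi-stage platform for (semi-)automatic 2D surgical planning of
    knee ligament reconstruction (MPFL, ACL, PCL) on lateral radiographs. Stage A
    detects anatomical features (bone segmentations, keypoint and line heatmaps)
    with a multi-task hourglass network trained with uniform or gradient-normalized
    task weighting; Stage B decodes the spatial encodings into geometric objects
    (sub-pixel keypoints, polylines, closed polygons, contour subsections); Stage C
    executes parameterized planning blueprints (Schoettle point, Bernard quadrant,
    Staeubli/Rauschning AP fractions, Johannsen transtibial guidewire) with
    deterministic, user-editable re-execution. A synthetic lateral knee phantom
    generator with exact analytic ground truth supports training and evaluation
    without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    jsonlite,
    mgcv,
    minpack.lm,
    png,
    utils,
    tibble,
    EBImage
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
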