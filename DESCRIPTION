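Package: pmaa
Title: Parametric Metal Artifact Avoidance for Intraoperative Cone-Beam CT
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Plans C-arm scan trajectories that avoid metal artifacts in
    intraoperative cone-beam CT. Pedicle screws are localized by
    triangulating head/tip keypoints from two calibrated scout views,
    modeled as ellipsoidal surrogates, and candidate tilted circular
    orbits are scored by the maximum X-ray path length through any
    implant. The analytic centroid-chord scorer makes the per-view cost
    proportional to the number of implants only; per-pixel rendered and
    voxel-mask raytracing scorers are included as reference baselines.
    A 95%-improvement heuristic selects the smallest practical tilt.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
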