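Package: glenplan
Title: Glenoid Baseplate Rotation and Bi-Cortical Screw Planning for
    Reverse Shoulder Arthroplasty
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Geometric planning pipeline for glenoid-side fixation in
    reverse total shoulder arthroplasty. Provides watertight triangle-mesh
    handling with ray-mesh intersection, anatomical coordinate frames built
    from scapular landmarks, glenoid morphometrics (anterior-posterior
    width, cranial-caudal diameter, version, inclination) with study-style
    exclusion filters, a parametric synthetic scapula generator with
    analytic ground truth and a cohort sampler, a metaglene baseplate and
    variable-angle screw trajectory model, per-case grid optimization of
    glenoid roll angle and screw angulation for maximal bi-cortical screw
    length under notch keep-out constraints, and cohort-level validation
    comparing patient-specific optima against calculated-average and
    rounded-average angle prescriptions with paired tests and correlations.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
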