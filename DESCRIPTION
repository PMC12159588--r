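Package: hipsweep
Title: Patient-Specific Hip Range-of-Motion and Impingement Simulation After Total Hip Arthroplasty
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates bony range of motion (BROM) after total hip arthroplasty from
    triangle meshes of the pelvis, femur and implant components. Builds ISB-style pelvic
    and femoral coordinate frames from anatomical landmarks, places the acetabular cup and
    liner from radiographic inclination/anteversion, poses the pelvis by pelvic tilt, and
    sweeps the femur through six hip motions in 0.5 degree increments until a
    BVH-accelerated triangle-mesh collision check detects impingement, which is classified
    as implant-to-implant, implant-to-bone or bone-to-bone. Includes a cohort statistics
    layer (ROM-vs-pelvic-tilt regression, benchmark crossings, clinical-relevance
    categories, impingement-type shift tables, paired and Welch t tests) and a synthetic
    data module (parametric watertight hip geometries, an analytic ball-in-cup fixture
    with closed-form limits, and pelvic-tilt cohort generators) so the whole pipeline is
    testable without patient CT data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
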