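Package: kneeplan
Title: In Silico Gap-Balanced Preoperative Planning for Total Knee Arthroplasty
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for in silico preoperative planning of total knee
    arthroplasty (TKA) on triangle-mesh bone and implant models. Places the
    tibial component by maximizing a penalized coverage index under rotation
    and overhang constraints via simulated annealing, constructs a
    morphology-based (measured-resection) femoral reference plan, and
    optimizes the femoral component pose with CMA-ES to balance medial and
    lateral joint gaps across the full flexion range using subject-specific
    flexion kinematics. Includes a piecewise nonlinear collateral-ligament
    tension model with wrapping-path length computation, a parametric
    synthetic-knee generator with controllable varus deformity for end-to-end
    testing, and paired nonparametric comparison of planning strategies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    igraph
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
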