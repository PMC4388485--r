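Package: driftact
Title: Drift-Diffusion Decision Making Coupled to Action Kinematics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates two-alternative forced choice as a drift-diffusion
    evidence accumulator coupled to a constant-speed two-dimensional action
    system. Four decision-action architectures are provided: serial action
    after decision completion, changes of mind during movement, continuous
    action preparation via an interpolated action focus, and preparation with
    a position-dependent commitment term feeding back into the effective
    evidence. Includes mouse-tracking style trajectory analytics (area to
    the chosen-target line, y-averaged mean trajectories, initial and final
    angles from vertical, area-under-curve curvature), boundary sweeps
    tracing speed-accuracy frontiers, and bisection calibration of the
    decision bound to a target mean response time. Batch simulation is
    reproducible through per-trial seed substreams and a compiled inner loop.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
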