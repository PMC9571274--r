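Package: skelwarp
Title: Skeletal Behavior Recognition by Joint-Angle Features and Dynamic Time Warping
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Template-matching recognition of human behaviors from 32-joint
    depth-sensor skeleton streams. Bone feature vectors are built by four
    selection schemes (whole-body or action-local joints, connected between
    adjacent joints or anchored at the pelvis), per-frame joint-angle
    differences between a standard and a test sequence are reduced to a
    scalar cost (sum, mean or maximum), the two sequences are aligned by
    unconstrained dynamic time warping, and the optimal-path cost is mapped
    to a percentage similarity used to flag unsafe behaviors against a
    threshold. Includes a forward-kinematic generator of synthetic motion
    sequences for five unsafe and two safe behaviors, CSV/JSON input-output,
    an evaluation harness, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    readxl,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
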