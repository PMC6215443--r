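Package: trabpose
Title: Inferring Bipedal Hindlimb Posture from Cancellous Bone Fabric
Version: 0.1.0
Authors@R:
    person("trabpose", "maintainers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A desk-scale implementation of the reverse trajectorial
    approach to postural inference in extinct bipeds.  Given a
    parameterized single-hindlimb musculoskeletal model and a field of
    cancellous-bone fabric axes, the package searches for the
    quasi-static characteristic posture that minimizes the angular
    deviation between compressive principal-stress axes (from a
    beam-theory bone-loading surrogate) and primary fabric axes within
    anatomical regions of interest.  Includes synthetic limb templates
    at three body-size scales, a Watson-distribution fabric simulator
    with known ground truth, static optimization of muscle activations,
    mid-shaft bone-loading metrics, normalized muscle-moment analysis,
    stereonet projection, and cross-species parameter reports.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
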