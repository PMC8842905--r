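Package: cephmorph
Title: Cephalometric Morphology Templates from 2-D Landmark Configurations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for landmark-based analysis of lateral cephalograms:
    triple-digitization calibration with a recalibration flag, magnification
    correction, rigid registration into the sella-origin / sella-nasion frame,
    a declarative catalog of angular and linear cephalometric measurements,
    clustering of landmark configurations into mean-coordinate morphology
    templates (CMTs), linear discriminant classification functions with
    leave-one-out cross-validation, a rule-based 21-template diagnostic system,
    pre/post treatment-change evaluation, and a fully synthetic landmark-cohort
    generator with stored ground truth for recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    cluster,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    MASS
Config/testthat/edition: 3
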