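Package: xcski
Title: Sub-Technique Identification in Classical Cross-Country Skiing from Inertial Sensors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies classical cross-country skiing sub-techniques (diagonal
    stride, double poling, double poling with kick, herringbone, rotational
    kicks) from tri-axial gyroscope and accelerometer recordings on both arms
    and both skis.  Implements windowed motion-component estimators (arm
    correlation and motion energy, independent leg motion, kick rotation,
    gravity-based ski roll/pitch and a herringbone orientation estimate),
    rule-based decision functions with configurable tolerances that assign
    exactly one sub-technique per sample, cycle segmentation and cycle-level
    majority labelling, confusion-matrix evaluation against expert reference
    labels, and a seeded synthetic multi-sensor session generator for testing
    the full pipeline without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
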