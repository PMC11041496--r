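Package: spirobreath
Title: Breath Segmentation and Validity Classification for Incentive
    Spirometer Sensor Streams
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the data stream produced by an optical add-on device
    for volumetric incentive spirometers. Parses time-stamped discrete
    flow-level (0-3) and volume-level (0-10) sensor logs, segments them into
    breaths using zero-flow boundary rules, classifies each breath as valid
    or invalid against five volume and timing criteria, and computes
    per-breath metrics (maximum flow and volume levels, ascent and descent
    rates). Includes device profiles for the Voldyne 5000 and Voldyne 2500
    spirometers, BTPS (body temperature, pressure, saturated) volume
    correction, flowmeter dead-volume calibration, a seedable synthetic
    sensor-stream simulator with ground-truth labels for every validity rule,
    and confusion-matrix evaluation (sensitivity, specificity, accuracy)
    with level-wise summary statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
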