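Package: acidnav
Title: Two-Threshold Simulation and Statistics of Acidic pH Avoidance
    Navigation in Caenorhabditis elegans
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Stochastic agent-based simulator of acidic pH avoidance
    navigation in the nematode Caenorhabditis elegans under the
    two-distinct-threshold model, in which gradual curves (klinotaxis) and
    abrupt reversals (klinokinesis) are each triggered with a sigmoid
    probability of the sensed pH around a maneuver-specific threshold.
    Includes piecewise-linear pH gradient fields fitted from strip
    measurements or generated parametrically, the behavioral statistics
    pipeline for avoidance-event tables (angle-binned choice ratios with
    Pearson correlation, distance histograms, F and Student's t
    comparisons), an exhaustive parameter grid search scored against
    reference summary statistics, and synthetic-data generators for both
    gradients and event tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
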