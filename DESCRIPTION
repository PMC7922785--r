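Package: wristpa
Title: Wrist Accelerometry and Calorimetry Validation Pipeline
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for validating wrist-worn accelerometers against a
    criterion accelerometer and portable indirect calorimetry. Converts raw
    tri-axial acceleration to ENMO (Euclidean norm minus one), classifies
    physical-activity intensity per second with milli-g cut-points, collapses
    to 60-s epochs, detects non-wear time with the Choi algorithm, turns
    breath-level VO2 into MET-classified minutes, aligns the streams on a
    shared wear mask, and computes a method-agreement suite (Pearson r, mean
    absolute percent error, Bland-Altman limits of agreement, 90% confidence
    intervals, and minimum equivalence zones). A synthetic-data module
    simulates co-worn device streams and breath data with known ground truth
    so the whole chain is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
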