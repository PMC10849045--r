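Package: minidetect
Title: Detection and Kinetic Analysis of Miniature Synaptic Events
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Headless toolkit for the analysis of spontaneous miniature
    postsynaptic events (mEPSCs/mEJCs and their voltage-clamp or
    current-clamp counterparts) in electrophysiological recordings.
    Implements a template-free detection algorithm based on windowed
    extremum search and a backward moving-average onset criterion, with
    single-exponential decay fitting, compound (overlapping) event
    resolution by decay subtraction, and kinetic acceptance filters.
    Includes a synthetic-recording simulator with analytic ground truth
    (double-exponential and linear-rise events, sine, correlated Gaussian
    and mains-hum noise), trace preprocessing (boxcar and zero-phase
    Bessel filtering, baseline subtraction, sweep averaging), evoked
    response summaries, and a validation harness that matches detections
    to ground truth and reports parameter-recovery statistics.
License: MIT
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
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
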