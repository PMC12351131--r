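Package: cardiocycle
Title: Statistical-Cycle ECG Analysis for Detecting Epileptic Brain Activity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting the cardiac signature of epileptic brain
    activity from single-lead ECG. Recordings are conditioned (resampling,
    zero-phase Butterworth bandpass, amplitude normalization, edge trimming),
    R-peaks are located with the Pan-Tompkins detector or taken from
    annotation files, and the signal is cut into fixed one-second
    "statistical cycles" around each R-peak. Per-cycle moment features are
    computed about either the mean or -- the robust variant -- the median
    (median variance, median skewness, median kurtosis), and cycles are
    classified healthy versus epilepsy with a small multilayer perceptron
    under patient-grouped cross-validation. A seeded synthetic-ECG generator
    with a physiological noise model (powerline, baseline wander, EMG,
    electrode motion, contact loss, instrumentation noise) makes every stage
    testable without access to clinical databases. Reads and writes WFDB-style
    and CSV recordings with R-peak annotation sidecars.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    grDevices,
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
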