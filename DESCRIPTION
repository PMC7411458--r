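Package: mmtqrs
Title: Adaptive Max-Min Threshold R-Wave Detection for Exercise ECG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Lightweight real-time QRS (R-wave) detection for single-lead
    exercise electrocardiograms. Implements a causal preprocessing chain
    (50 Hz notch, order-40 equiripple FIR low-pass), sliding-window median
    baseline correction, a signed-square window-difference transform, and
    an adaptive Max-Min Threshold (MMT) detector with RR-interval error
    correction and amplitude-trend threshold freezing. Includes WFDB and
    CSV readers, a synthetic exercise-ECG generator with ground-truth beat
    locations, and tolerance-matched sensitivity / positive-predictivity
    scoring of beat detections.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
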