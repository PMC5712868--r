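Package: ecgwatch
Title: Integrated Arrhythmia Detection for Single-Lead Wearable ECG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: An integrated pipeline for detecting arrhythmias in single-lead
    electrocardiogram recordings of the kind produced by wearable monitors.
    Reads WFDB-format records and MIT-style annotations, resamples to a
    common 200 Hz time base, detects QRS complexes with a Hamilton-style
    adaptive-threshold detector, classifies ventricular premature complexes
    from QRS width and prematurity, detects atrial fibrillation per 5-minute
    window from the ectopy-corrected RR series via heart-rate symbolization,
    base-64 word values and sample entropy, classifies atrial premature
    complexes with a single-hidden-layer perceptron, and detects ventricular
    fibrillation per 2-second segment from periodogram band-peak ratios.
    Includes an ANSI/AAMI EC57-style evaluator (beat, episode and duration
    statistics with gross and average aggregation) and a seeded synthetic
    ECG generator with ground-truth annotations so the whole pipeline is
    testable without access to clinical databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    nnet,
    optparse,
    yaml
Config/testthat/edition: 3
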