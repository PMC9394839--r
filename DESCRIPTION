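Package: spindleloop
Title: Real-Time Sleep Spindle Detection and Closed-Loop Stimulation Toolkit
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale toolkit for closed-loop detection of sleep spindles
    in single-channel EEG. Provides a seeded generator of spindle-bearing
    synthetic EEG with simulated multi-expert consensus scores, EDF and
    annotation input/output, a streaming two-branch causal preprocessing
    pipeline (band-pass and notch FIR filtering, online exponential-moving-
    average standardization, envelope extraction) with exact delay
    bookkeeping, a lightweight time-dilated convolutional-recurrent (CNN+GRU)
    detector trained on consensus-score labels, a subject-wise evaluation
    protocol with sample-level metrics, a Pareto-front hyperparameter search
    trading trainable-parameter count against detection error, and an online
    stimulation policy with refractory logic and event-level scoring that
    accounts for hardware and software delays.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    signal,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
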