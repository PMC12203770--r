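Package: nldbench
Title: Offline Benchmarking of Linear and Nonlinear Intracortical Finger Velocity Decoders
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.com")
Description: Simulates two degree-of-freedom finger-movement sessions with
    spiking-band-power (SBP) neural features under a known kinematic encoding,
    and benchmarks velocity decoders on them offline: ridge regression, a
    dual-state movement/posture decoder, a temporally-convolved feedforward
    network (TCN) and its regularization ablations, an LSTM, and ReFIT-style
    velocity relabeling with fine-tuning. Includes the SBP feature-extraction
    chain (decimate, bandpass, rectify, bin), trial-level cross-validation
    fold construction, multi-context dataset assembly, and the evaluation
    machinery used to compare decoder families: mean-squared error, speed-
    regime statistics, velocity-distribution KL divergence, median prediction
    deviation, and Fitts-law trial metrics, with the accompanying statistical
    tests.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    MASS,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
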