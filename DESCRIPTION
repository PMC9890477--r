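Package: amygdecode
Title: Sliding-Window Population Decoding of Facial Expressions from Spike Trains
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidy pipeline for single-neuron and population analyses of
    trial-aligned extracellular spike trains recorded while monkeys viewed
    facial expressions. Provides sliding-window spike counting, Friedman
    time-courses of expression sensitivity with shuffle-calibrated nulls,
    one-vs-rest linear support-vector-machine population decoding with ROC/AUC
    profiling, classifier-weight excitation/suppression analysis with latency
    estimation, and spatial-frequency reference-frame shift-index analysis.
    Includes an inhomogeneous-Poisson spike-train simulator that emulates the
    response structure these analyses assume, so every stage is testable
    without recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
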