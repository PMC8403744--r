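Package: transadapt
Title: Simulation and Analysis of Trans-Saccadic Contrast Adaptation Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to simulate and analyse gaze-contingent contrast-cancellation
    experiments on trans-saccadic luminance adaptation. Generates counterbalanced
    trial schedules for five experiment designs, simulates 1000 Hz gaze traces and
    two-alternative forced-choice contrast judgments from a generative observer
    whose point of subjective equality depends on adaptation duration and
    postsaccadic blank duration, detects saccades offline with velocity and
    acceleration thresholds, applies per-trial exclusion rules based on fixation
    stability and saccade-amplitude accuracy, and recovers adaptation effects via
    maximum-likelihood psychometric fits (PSE, JND), running-average build-up
    curves, and logarithmic decay fits.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
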