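Package: metacrit
Title: Optimal Type 2 Criterion Setting in Signal Detection Theory
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Normative analysis of confidence ("type 2") criterion setting in
    equal-variance signal detection theory. Provides the forward model for
    type 1 and type 2 response rates, accuracies and expected rewards;
    closed-form optimal type 1 and type 2 criteria under four objectives
    (type 2 accuracy, type 2 reward, calibration of confidence to a target
    accuracy, and maximizing the difference between type 2 hit and false
    alarm rates); a brute-force outcome-curve oracle; generative process
    models of suboptimal metacognition (type 2 noise and type 2 signal loss)
    with exact bivariate-normal and Monte-Carlo engines; and maximum
    likelihood estimation of meta-d' and the M-ratio from binary-confidence
    count data. A command-line interface exposes the main computations.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    mvtnorm,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
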