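Package: serialdep
Title: Serial Dependence and Distractor Suppression in Orientation
    Adjustment Tasks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Simulation and analysis pipeline for serial-dependence
    experiments in which an orientation adjustment task is interleaved
    with a visual discrimination task containing an ignored, oriented
    distractor. Provides a parameterized synthetic observer that
    generates trial tables with the full experimental design
    (random vs. fixed distractor location, 50% distractor presence,
    derivative-of-Gaussian bias kernels, lapses, inverse-Gaussian
    reaction times), the trial- and participant-level exclusion rules,
    a derivative-of-Gaussian regression model family with grid search
    over kernel widths and BIC model comparison, similarity-split
    coefficient contrasts, and an inverse-Gaussian mixed-effects model
    of discrimination reaction times (attentional capture).
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    pracma,
    stats,
    utils
Suggests:
    lme4,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
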