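Package: stmcit
Title: Simulation and Analysis of the Gaze-Based Short-Term-Memory Concealed Information Test
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the short-term-memory variant of the concealed
    information test (STM-CIT), in which concealed face familiarity is
    inferred from eye movements during a four-face memorization display.
    The package generates counterbalanced 64-trial schedules, simulates
    1,000-Hz gaze recordings with calibrated orientation/avoidance
    effects, parses raw samples into saccades, blinks and fixations with
    area-of-interest assignment, computes dwell-time time courses,
    phase-wise preference indices and per-face feature vectors, runs the
    within- and between-participant RBF-SVM classification protocol with
    its random-tag chance baseline, and provides the frequentist
    inferential stage (one-sample location tests, mixed ANOVA with
    partial eta squared, Tukey post hoc comparisons).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    e1071,
    emmeans,
    generics,
    ggplot2,
    jsonlite,
    pROC,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
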