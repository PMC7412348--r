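Package: gaitrp
Title: Recurrence-Plot Imaging and Classification of Neurodegenerative Gait
Version: 0.1.0
Authors@R:
    person("Robin", "Walker", email = "rwalker@example.org",
           role = c("aut", "cre"))
Description: Tools for screening neurodegenerative disease (amyotrophic
    lateral sclerosis, Parkinson's and Huntington's disease) from vertical
    ground reaction force (vGRF) gait recordings. Implements overlapping
    rectangular windowing of two-channel force traces, unthresholded
    recurrence-plot encoding of each window as a gray-level image,
    full-principal-component feature enhancement, deterministic image
    feature extraction backends with a linear support vector machine, and
    leave-one-out cross-validation reporting accuracy, sensitivity,
    specificity, AUC and Youden's index per force channel. A synthetic
    gait-force simulator with class-specific stride and stance statistics
    makes the whole pipeline runnable and testable without any data
    download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
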