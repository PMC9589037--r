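Package: connectodyn
Title: Phase-Aligned Dynamic Functional Connectivity for Task fMRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tracks how functional brain connectivity evolves over the
    seconds of a widely spaced event-related fMRI task. Frames are aligned
    by their position within a trial, stacked per (frame, stimulus)
    condition, and a connectotype - a regularized linear model expressing
    each region's signal as a weighted sum of all other regions - is fitted
    per condition. Network-pair-level time-by-stimulus interactions are then
    tested with repeated-measures ANOVA under Box-Cox normalization,
    Mauchly/Greenhouse-Geisser sphericity handling and family-wise
    correction, with a Pearson-correlation baseline on identical frames. A
    seeded synthetic BOLD generator with plantable connectivity interactions
    supports validation, calibration and power analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tibble,
    utils,
    withr
Suggests:
    MASS,
    car,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
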