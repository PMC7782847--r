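Package: napcue
Title: Simulation and Analysis of Multi-Item Targeted Memory Reactivation Nap Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end pipeline for targeted memory reactivation (TMR)
    sleep studies that cue sets of one, two, or six spatially learned items
    with a single sound. Generates the constrained experimental design
    (candidate grid layouts, learning-block schedules, cued/non-cued
    balancing, sleep cue sequences), simulates pre- and post-sleep placement
    behaviour under competing reactivation hypotheses (parallel reactivation
    versus divided, random-subset, or biased-subset limited-capacity models),
    scores placements with phantom-location swap classification, and runs the
    behavioural statistics (within-subject ANOVAs, Tukey HSD, BIC Bayes
    factors, pre-sleep regression adjustment, subsample robustness screens,
    permutation-tested intraclass correlations). A companion EEG stack
    synthesizes cue-locked NREM recordings and analyses them with cue-locked
    spectrograms, Bonferroni-thresholded time-frequency clusters, an
    RMS-threshold sleep-spindle detector, and linear mixed models of
    set-size modulation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    lme4,
    lmerTest,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
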