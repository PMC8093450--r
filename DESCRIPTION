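Package: cogload
Title: Physiological and Performance-Based Estimation of Cognitive Workload
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Metrics and statistical tooling for estimating operator cognitive
    workload from eye-tracking, electroencephalography (EEG) and manual-control
    recordings. Implements pupil-diameter spectral workload indices (L1 norm of
    the 1-5 Hz single-sided spectrum, pupil-diameter standard deviation,
    low-pass-filter summary), velocity-threshold (I-VT) fixation
    classification, the nearest-neighbour index of gaze-fixation dispersion,
    saccadic-intrusion detection, Welch band-power summaries for the canonical
    EEG bands, and inceptor duty-cycle / aggressiveness / tracking-error
    performance metrics. A nonparametric repeated-measures harness (outer-fence
    outlier removal, Anderson-Darling normality gate, Friedman omnibus,
    pairwise Wilcoxon signed-rank, Spearman rank correlation, one-way
    repeated-measures ANOVA) compares task conditions and correlates metrics.
    A synthetic multi-condition study generator with a known workload effect
    map makes the full pipeline verifiable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    signal,
    stats,
    utils
Suggests:
    nortest,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
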