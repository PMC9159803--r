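Package: ipastr
Title: Lifespan Analysis of Interleaved Pro/Anti-Saccade Behavior
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for the interleaved
    pro/anti-saccade task (IPAST). Generates synthetic 500 Hz gaze traces
    from a race model of automated and voluntary saccade programming,
    detects saccades with a per-trial dynamic speed threshold, classifies
    trials into the anticipatory/viable/non-compliance taxonomy, applies
    cohort-level quality control, computes seven behavioral measures
    including the voluntary override time (VOT), fits penalized-spline
    generalized additive models of each measure on age, locates significant
    periods of lifespan change from simultaneous confidence bands on the
    fitted trend's first derivative, builds percentile growth curves, and
    reports age-controlled Spearman correlations between measures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    mgcv,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
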