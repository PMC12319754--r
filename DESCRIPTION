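Package: dfncstates
Title: Dynamic Functional Network Connectivity State Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Sliding-window dynamic functional network connectivity (dFNC)
    analysis of network component time courses: motion quality control and
    time-course post-processing (detrending, despiking, Butterworth low-pass
    filtering, temporal normalization), tapered sliding-window connectivity
    with L1-penalized (graphical lasso) precision estimation and Fisher
    z-transformation, k-means brain-state clustering with elbow-based model
    selection, state occupancy/dwell/transition metrics, and random-intercept
    mixed-model pre/post contrasts for three-arm randomized trials. Includes a
    Markov-switching multivariate Gaussian cohort simulator with ground-truth
    state sequences for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    lme4,
    lmerTest,
    emmeans,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
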