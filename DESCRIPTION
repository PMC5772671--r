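Package: megstream
Title: Decoding Bistable Auditory Perceptual States from MEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for decoding bistable auditory
    streaming percepts (gallop versus segregated) from magnetoencephalography.
    Provides a synthetic-data generator for continuous A-B-A triplet
    experiments with lognormal percept dynamics and a planted state-dependent
    evoked effect; preprocessing (Butterworth filtering, downsampling,
    epoching, switch-adjacent trial exclusion, robust averaging); behavioral
    analysis of percept dominance durations; spatio-temporal SVD feature
    reduction; canonical variate analysis with Wilks' Lambda inference;
    linear and RBF support-vector classification with repeated
    cross-validation, two-stage grid search and binomial above-chance
    testing; minimum-norm source inversion with top-variance and
    region-of-interest analyses; and group-level time-course statistics with
    cluster-based sign-flip permutation correction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    e1071,
    stats,
    utils,
    yaml,
    jsonlite,
    nortest
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
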