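Package: serialdep
Title: Serial-Dependence Analysis for Behavioral and Epoched M/EEG Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for estimating serial dependence in continuous 2-D
    spatial tasks and tracing its neural substrate in epoched
    electrophysiological recordings.  Provides behavioral serial-bias
    regression and weighted-choice mixed-model comparison, trial-wise
    representational similarity decoding of location information,
    estimation of representational axes and their past-present cosine
    alignment (including a leave-one-out trial-level variant), sign-flip
    cluster-based permutation inference with optional cross-region
    correction, neuro-behavioral coupling analyses, and a synthetic-data
    generator that plants known bias coefficients and known axis geometry
    so that every stage of the pipeline can be validated by parameter
    recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    lme4,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
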