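Package: pulsecue
Title: Amplitude Modulation Analysis of Cue-Locked Neural Responses in
    Pulsatile Evidence Accumulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for studying how visual-cortical responses to pulsatile
    sensory cues are modulated during evidence accumulation. Simulates
    virtual T-maze sessions (spatially Poisson cue trains with a same-side
    refractory period, kinematics, choice behavior) and forward-models
    calcium fluorescence traces as impulse responses convolved with a
    GCaMP-like indicator kernel. Provides per-cell deconvolution of
    cue-locked response amplitudes with small-sample AICc scoring and a
    shuffle-based cue-locking significance test, a family of Gamma-likelihood
    amplitude-modulation models (angular receptive field and running-speed
    null model, stimulus-specific adaptation, choice, and cumulative
    cue-count models) with AICc model selection and averaging, population
    decoding of task variables with trial-level permutation nulls,
    Benjamini-Hochberg correction and uncorrelated task-variable modes via
    polar decomposition, and behavioral metrics (psychometric sigmoid,
    spatially binned evidence logistic regression, quantile-based summary
    statistics and Jeffreys binomial intervals).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    pracma,
    e1071,
    jsonlite,
    minpack.lm,
    glmnet
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
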