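Package: cogscreen
Title: Digitized Cognitive, Motor and Speech Impairment Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Scoring and classification toolkit for self-administered
    neurocognitive screening on touch-screen devices. Implements automatic
    scoring of sixteen digitized tasks (finger tapping, Archimedean spiral
    tracing, SAGE-style cognitive items, clock drawing, trail making,
    match-puzzle problem solving, voice recording and daily energy
    expenditure), geometric primitives (discrete Frechet distance,
    neighbor-matching graph similarity), Jaro-Winkler inexact answer
    matching, speech feature extraction (five pitch estimators, MFCC,
    gammatone cepstral coefficients, spectral descriptors, a wavelet
    scattering transform), a 238-feature session schema, a synthetic cohort
    generator with class-conditional impairment effects, and a hybrid
    healthy-vs-impaired classification layer (AdaBoost.M1, a 13-member
    probability-fusion ensemble, feature selection and a full confusion
    metric suite).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    tibble,
    dplyr,
    purrr,
    rlang,
    ggplot2,
    stats,
    utils,
    MASS,
    e1071,
    kernlab,
    randomForest,
    rpart,
    nnet,
    generics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
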