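Package: microdyn
Title: EEG Microstate Dynamics and Omega Spatial Complexity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Resting-state EEG analysis of microstate dynamics and spatial
    complexity. Segments multichannel EEG into four canonical microstate
    classes (A-D) by extracting topographies at global field power peaks,
    clustering them with the topographic atomize-and-agglomerate
    hierarchical clustering algorithm (T-AAHC), and back-fitting the
    prototypes by maximal polarity-invariant spatial correlation; reports
    per-class duration, occurrence, coverage and the transition-probability
    (syntax) matrix. Computes omega spatial complexity - the exponential of
    the Shannon entropy of the normalized eigenvalue spectrum of the channel
    covariance matrix - globally and over anterior/posterior electrode
    subsets. Includes a semi-Markov synthetic-cohort generator with known
    ground truth, a preprocessing chain (montage reduction, resampling,
    zero-phase band-pass and notch filtering, epoching, average reference),
    and the group-level statistics used in this literature (ANCOVA with an
    age covariate, mixed-design repeated-measures ANCOVA, partial eta
    squared, Bonferroni correction).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    car,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
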