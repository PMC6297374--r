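Package: synstab
Title: Local Dynamic and Orbital Stability of Muscle-Synergy Activations in Gait
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to quantify the stability of muscle-synergy activations
    during treadmill walking from multi-channel surface electromyography
    (EMG). The pipeline filters and time-normalizes EMG into a muscles by
    gait-phase matrix, extracts muscle synergies by non-negative matrix
    factorization with cross-validated variability-accounted-for (VAF) model
    selection and a shuffled-data control, reconstructs delay-coordinate
    state spaces for each synergy activation (average mutual information
    delay, false-nearest-neighbor dimension), and estimates short-term
    maximum Lyapunov exponents (Rosenstein nearest-neighbor divergence) and
    maximum Floquet multipliers (linearized Poincare maps at each percent of
    the gait cycle).  A synthetic-data module generates surface-EMG-like
    recordings with known synergy structure and dynamical-systems oracles
    with known stability constants, so every stage is verifiable without
    laboratory recordings.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    signal,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
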