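Package: gammastates
Title: Linking Spontaneous Low-Frequency Brain-Network States to Stimulus-Induced Gamma Responses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to relate spontaneous sub-35 Hz brain-network dynamics, inferred
    from parcel-level electrophysiological recordings with a time-delay embedded
    Gaussian hidden Markov model (TDE-HMM), to narrow-band gamma responses induced
    by visual stimulation. Provides a synthetic cohort generator with planted state
    dynamics and state-coupled gamma bursts, preprocessing (band-pass filtering,
    per-subject standardisation, baseline extraction, sign alignment), maximum
    likelihood TDE-HMM inference with forward-backward posteriors, state-weighted
    multitaper spectra and band-limited power maps, state dynamics summaries
    (fractional occupancy, lifetimes, interval times), cross-model state matching
    by power-map correlation and hierarchical clustering, time-frequency gamma
    quantification with individual peak detection and percent-change baselining,
    and the inferential layer: permutation Spearman correlations, soft-assigned
    trial grouping with Friedman and post-hoc tests, pseudo-state binning, and a
    subject-level bootstrap comparison of between- and within-subject effects.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
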