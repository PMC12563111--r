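Package: phasetopo
Title: Phase-Space Topology Features for Multichannel EEG
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Feature extraction for emotion-related EEG built on the topology of
    reconstructed phase-space trajectories. Provides delay-embedding parameter
    selection (minimum cross prediction error for the delay, the
    Grassberger-Procaccia scale statistic for the dimension), locally linear
    embedding of trajectories to the plane, sixteen trajectory-topology
    descriptors plus band-wise differential entropy, gain-based feature and
    electrode-channel selection, chronological and leave-one-subject-out
    classification protocols, and a seeded synthetic-EEG generator for
    end-to-end validation without restricted recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    signal,
    MASS,
    e1071,
    class,
    ranger,
    xgboost,
    jsonlite,
    Rcpp,
    stats,
    utils,
    grDevices
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
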