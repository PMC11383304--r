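Package: phondecode
Title: Phoneme Distinctiveness Analysis for Continuous-Speech EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for quantifying the cortical distinctiveness of phoneme
    representations from EEG recorded during continuous-speech listening.
    Derives phoneme-related potentials (PRPs) with inventory filtering and
    instance capping, decodes phoneme identity with a compact convolutional
    network under cross-validation, attributes classifier decisions to
    electrodes and time points with DeepLIFT (Rescale rule), aligns neural
    dissimilarity structure with phonological distinctive features via
    representational similarity analysis, estimates neural tracking of the
    acoustic envelope and onsets with boosting temporal response functions,
    and provides the group-level statistical layer (cluster-mass permutation
    tests, rationalized arcsine units, backward stepwise AIC regression).
    A synthetic-data generator with known ground truth makes every stage
    testable without any recording.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    signal,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
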