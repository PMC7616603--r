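Package: scenersa
Title: Model-Based Representational Similarity Analysis of EEG
    Scene-Object Congruency
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for time-resolved representational similarity analysis
    (RSA) of epoched EEG recorded while observers view objects embedded in
    semantically congruent or incongruent scenes.  Builds binary congruency
    model dissimilarity matrices and per-condition semantic model matrices
    from concept-by-feature property norms, computes per-timepoint neural
    dissimilarity matrices with correlation distance across channels,
    relates model and neural geometry with Spearman correlation, and
    performs group random-effects inference with sign-flip cluster-mass
    permutation tests (one-sample and paired).  Includes an HDF5 epoch
    container with reader and writer, automated noisy-trial rejection,
    baseline correction, and a synthetic-data generator that produces
    counterbalanced designs, sparse property norms and multi-subject
    epochs with known representational geometry injected into chosen
    latency windows, so the whole pipeline can be validated by parameter
    recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    rhdf5,
    jsonlite,
    stats,
    graphics,
    grDevices,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
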