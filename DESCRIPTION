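Package: anopeak
Title: Unsupervised Anomaly Detection in Multi-Source Genomic Peak Catalogues
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores ChIP-seq peaks in multi-source catalogues by how well the
    usual combinations of experimental series and transcriptional regulators
    explain them. Each candidate cis-regulatory module is represented as a
    position x dataset x regulator presence tensor and lossily compressed with
    a stacked multiview convolutional autoencoder; peaks that the learned
    source-combination patterns fail to reconstruct receive low anomaly
    scores. Includes group-bias normalization onto a 750-centered 0-1000
    scale, a Q-score for choosing the information budget, request-mask and
    gradient-ascent model interpretation, and an artificial-CRM simulator
    with known correlation groups for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
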