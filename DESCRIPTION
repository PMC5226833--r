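Package: vbdcmm
Title: Variational Bayes Double-Chain Markov Models for Single-Molecule
    Time Traces with Dynamic Disorder
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Decodes hidden kinetic regimes ("internal states") from
    single-molecule FRET-like time traces that exhibit dynamic disorder,
    i.e. slow switching between distinct conformational kinetics. Fits a
    double-chain Markov model by variational Bayes, selects the number of
    internal states with a label-degeneracy-corrected evidence bound,
    idealizes noisy traces with a Gaussian-emission hidden Markov model,
    decomposes decoded traces into homogeneous Markov components, scores
    decoding accuracy and time-scale separation, and clusters inter-basin
    kinetic arrows to reconstruct the connectivity of the underlying
    conformational landscape. Includes a two-layer Markov simulator for
    generating benchmark traces.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
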