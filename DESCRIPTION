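Package: txdecay
Title: Multi-Agent Simulation of the Cross-Talk Between mRNA Decay and RNA
    Polymerase II Elongation
Version: 0.1.0
Authors@R:
    person("txdecay", "developers", email = "txdecay@example.org",
           role = c("aut", "cre"))
Description: Discrete-tick spatial multi-agent simulation of a single
    transcribed gene in a two-compartment (nucleus/cytoplasm) cell, coupling
    RNA polymerase II elongation, backtracking and TFIIS rescue to
    cytoplasmic mRNA degradation by the Xrn1 decaysome and the Ccr4-Not
    complex. Implements two model generations (four Ccr4-Not action variants
    with optional Xrn1 initiation feedback and co-transcriptional mRNA
    imprinting, and a four-state polymerase machine with Xrn1- and
    Ccr4-enhanced elongation classes), an in-silico genetics harness
    (dst1, ccr4 and xrn1 deletions as zeroed agent pools), sign-matrix
    construction from replicate simulations via Student's t-tests, the
    hit/penalty matrix-comparison score used for model selection, and
    kinetic estimators for mRNA half-life from transcription shut-off
    time courses and for RNAPII speed from ChIP run-off profiles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
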