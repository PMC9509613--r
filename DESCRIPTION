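Package: seqgp
Title: Genomic Prediction with Preselected Sequence Variants in Pedigreed Lines
Version: 0.1.0
Authors@R:
    person("seqgp", "developers", email = "seqgp@example.org", role = c("aut", "cre"))
Description: A tested, reusable pipeline for studying genomic prediction with
    whole-genome sequence (WGS) variants preselected by association tests,
    compared against a nested marker array, in closed pedigreed livestock
    lines. Includes simulation of multi-line pedigreed populations with dense
    genotypes generated by gene dropping, pedigree and genomic relationship
    matrices, animal-model BLUP with VanRaden-style deregression of breeding
    values, a single-variant linear mixed-model association scan with a
    spectral REML solver, window-based variant preselection (top-per-window
    and chip-plus-significant strategies), a from-scratch BayesR mixture-prior
    Gibbs sampler with optional line effects, and the pedigree-aware
    training/testing design with accuracy and bias evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
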