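Package: concretome
Title: Low-Biomass 16S Community Analysis for Concrete and Built Environments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for longitudinal low-biomass 16S amplicon studies of
    concrete and similar built-environment substrates. Provides compositional
    co-occurrence inference (SparCC and proportionality rho), a multi-stage
    contaminant classifier driven by negative controls, correlation networks,
    laboratory-strain identity and edit-distance propagation, phylogenetic
    community metrics (Faith's PD, the UniFrac family including generalized
    UniFrac), permutation tests (PERMANOVA, dispersion, Mantel), indicator
    species analysis, spline-based differential-abundance intervals, seasonal
    trend decomposition, Gibbs-sampling microbial source tracking, and a
    synthetic-study generator with complete ground truth for validating every
    stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    Biostrings,
    jsonlite,
    Rcpp,
    splines,
    stats,
    utils,
    vegan
LinkingTo: Rcpp
Suggests:
    optparse,
    phyloseq,
    picante,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
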