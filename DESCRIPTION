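Package: msmbind
Title: Markov State Model Analysis of Protein-Ligand Binding Kinetics
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for quantifying protein-ligand recognition from
    trajectory data with Markov state models (MSMs): binary residue-ligand
    contact featurization, time-lagged independent component analysis
    (tICA), k-means microstate discretization, reversible maximum-likelihood
    transition-matrix estimation with implied-timescale lag selection,
    PCCA+ metastable coarse-graining, and transition-path-theory analysis
    (committors, reactive fluxes, pathway decomposition). Mean first
    passage times are converted to on/off rate constants, residence times
    and binding free energies. A synthetic-data module plants metastable
    kinetics in discrete chains and overdamped Langevin simulations of a
    diffusing ligand, and a well-tempered metadynamics engine on toy
    landscapes supports biased free-energy reconstruction and
    ligand-egress comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    igraph,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    bio3d,
    jsonlite,
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
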