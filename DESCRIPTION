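Package: halopi
Title: Halogen-Pi Sigma-Hole Interaction Energy Modelling
Version: 0.1.0
Authors@R:
    person("halopi", "maintainers", email = "halopi@example.org",
           role = c("aut", "cre"))
Description: Tools for modelling sigma-hole driven halogen-pi interactions
    between halobenzenes and benzene, the standard surrogate for the
    phenylalanine side chain. Provides systematic and random rigid-body pose
    generation over the benzene plane, a 30-component geometric descriptor
    (24 sorted atom-pair distances, 3 further distances, 3 angles), an
    analytic surrogate for quantum-chemical adduct formation energies so the
    pipeline is trainable at desk scale, a compiled feed-forward neural
    network regressor with Adam, learning-rate halving and early stopping,
    a Mahalanobis-distance applicability domain, and a PDB miner that finds
    halogen contacts to phenylalanine rings, applies sigma-hole geometry
    filters, and rebuilds matched halobenzene-benzene model complexes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    graphics,
    stats,
    utils,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
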