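Package: allonet
Title: Allosteric Communication Networks from Conformational Ensembles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Ensemble-analysis machinery for comparing effector- and
    temperature-induced allosteric activation in proteins: mutual-information
    generalized-correlation networks with eigenvector centrality, optimal and
    suboptimal signalling pathways on -log(rMI) weights, dynamical perturbation
    contact networks, secondary-structure persistency, essential-dynamics PCA,
    and amide-proton temperature-coefficient statistics. Ships a synthetic-data
    module that generates correlated Gaussian conformational ensembles,
    two-state perturbed ensemble pairs, toy all-atom topologies and
    temperature-series chemical-shift tables with known ground truth, so the
    whole pipeline is testable end to end without molecular-dynamics input.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    igraph,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    bio3d,
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
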