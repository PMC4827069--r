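Package: immunoSSA
Title: Stochastic Individual-Based Modelling of Tumour-Immune Coevolution
    Under Adoptive T-Cell Therapy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Exact stochastic (Gillespie) simulation of an individual-based
    model of melanoma under adoptive T-cell transfer therapy, in which cancer
    cells carry a genotype and a switchable phenotype, T-cells kill their
    target phenotype and release cytokines, and cytokines enhance phenotypic
    switching. Includes the deterministic large-population (quadratic ODE)
    limit with fixed-point location and linear stability analysis, invasion
    fitness of phenotype-structured mutants via the mean matrix of a
    multi-type branching process, analysis of total mutation rates under
    birth-reducing competition, and a therapy-experiment layer that runs
    replicate ensembles and classifies outcomes (cure, differentiated or
    dedifferentiated relapse, coexistence).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    deSolve,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
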