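Package: structmark
Title: Structural Network Biomarkers from Gene Expression Data
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Infers two-condition gene-association networks with the
    conservative causal core (C3NET) method, expands them into populations of
    gene-set-induced subgraphs, computes eigenvalue-based (graph energy,
    Estrada index, Laplacian energy) and entropy-based (information
    functionals, partition entropies, Balaban J) graph invariants as
    structural biomarkers, classifies network class membership with a
    polynomial-kernel support vector machine under cross-validation, and
    quantifies each invariant's discrimination power through degeneracy
    (ndv) counts. Includes a seeded synthetic-data generator for
    two-condition expression matrices with planted correlation modules and
    differentially expressed genes, so the whole pipeline is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
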