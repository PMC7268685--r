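Package: phylocong
Title: Phylogenomic Congruence Diagnostics for Partitioned Supermatrices
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Diagnostics for phylogenomic congruence assessment on partitioned
    supermatrices: matched-pairs symmetry tests (Bowker) and compositional
    heterogeneity scores (RCFV) with masking and decisiveness filtering,
    four-cluster likelihood mapping with signal-destroying data permutations,
    quartet support of a species tree against gene trees around every
    internode, and ancestral reconstruction of discrete characters on a fixed
    chronogram by Sankoff parsimony, Mk maximum likelihood and stochastic
    character mapping. Includes a seeded synthetic-data generator emulating
    non-random data coverage, lineage-specific compositional shifts, gamma
    rate variation and gene-tree discordance, so every stage is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    Rcpp,
    Matrix,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    phytools
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
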