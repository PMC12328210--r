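Package: coevocell
Title: Cross-Species Co-Evolution Analysis of Fetal-Maternal Cell Signalling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs the evolution of ligand-receptor signalling between
    fetal (placental) and maternal (uterine) cell types across a mammal
    phylogeny. Provides thresholded ligand-receptor interaction calling from
    multi-species pseudo-bulk and cell-level expression atlases, the allocrine
    ligand count (ALC) statistic with its ANOVA, Kleinberg hub/authority
    scores of cell-cell signalling graphs, binary and continuous ancestral
    state reconstruction (Sankoff parsimony under equal and gain-penalising
    cost schemes, Wagner parsimony, Brownian-motion generalised least
    squares), ancestral signalling network rebuilding, a null-model test for
    the disambiguation of ligand expression between fetal and maternal
    compartments, an escalation test based on phylogenetic independent
    contrasts of standardized expression (zTPM), and a synthetic multi-species
    atlas generator with planted ground truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    igraph,
    Matrix,
    methods,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    phytools
Config/testthat/edition: 3
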