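Package: paralogon
Title: Paralogon Detection, Duplication Dating and Ancestral Gene
    Repertoires After Whole-Genome Duplication
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for reconstructing the evolution of paralogous chromosome
    regions (paralogons) produced by the two basal vertebrate whole-genome
    duplications (2R) and the teleost-specific third round (3R). Builds
    conserved-synteny chromosome blocks around anchor genes, selects
    neighboring gene families by block co-occurrence, dates gene-family
    duplications to WGD time-windows by gene-tree/species-tree (LCA)
    reconciliation, assembles paralogons from 2R-dated paralog pairs, detects
    lineage-specific fissions and times post-3R translocations against a
    pre-3R outgroup, and reconstructs ancestral gene repertoires under Dollo
    parsimony. Includes a deterministic and a stochastic genome-evolution
    simulator that emit gene coordinate tables, congruent gene trees and a
    ground-truth event log for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    igraph,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
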