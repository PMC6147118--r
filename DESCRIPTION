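Package: sizeweb
Title: Individual Trait-Based Analysis of Quantitative Bipartite
    Flower-Visitor Networks
Version: 0.1.0
Authors@R:
    person("sizeweb", "developers", email = "sizeweb@example.org",
           role = c("aut", "cre"))
Description: Builds and compares quantitative bipartite plant-pollinator
    networks whose nodes are either species or functional-size classes of
    individually measured bees and flowers.  Provides linear trait
    imputation (proboscis length from intertegular distance, nectar holder
    depth from floral display size, with a 1 mm floor for open flowers),
    average-linkage (UPGMA) clustering of individuals into size nodes with
    constrained and optimal-k cuts, quantitative network metrics (weighted
    connectance, weighted nestedness WNODF, interaction evenness, H2' and
    d' specialization, species strength), fixed-margin (Patefield) and
    marginal-conserving null models with z-score tests, bipartite
    centrality, and a seeded synthetic-community generator so the whole
    pipeline is testable without field data.
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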