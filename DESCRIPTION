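Package: netmod
Title: Network Module Analysis for Herb-Target Protein Interaction Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: A network-pharmacology analysis pipeline: screens two-group
    expression profiles for differentially expressed genes, intersects
    herb-target and disease gene sets, builds a protein-protein interaction
    network from a confidence-thresholded edge list, characterises its
    topology (clustering, diameter, centralization, heterogeneity,
    power-law degree-distribution fit, path-length distribution), derives a
    critical subnetwork by repeated median filtering on degree, betweenness
    and closeness, intersects triple-centrality top-k rankings into hub
    genes, detects dense molecular complexes with an MCODE implementation,
    and runs per-module hypergeometric over-representation analysis against
    GMT gene-set collections. Ships seeded synthetic-data generators
    (scale-free graphs, planted dense modules, planted differential
    expression, overlapping target-set bundles, planted GMT terms) so every
    stage can be validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    limma,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
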