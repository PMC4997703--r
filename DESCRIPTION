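Package: EnPIN
Title: Ensemble Centrality over Correlation-Thresholded Protein Interaction Networks
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Ranks proteins by essentiality with an ensemble of centrality
    measures computed over a series of co-expression-thresholded
    protein-protein interaction networks. From a base interaction network and
    a gene expression compendium, per-edge Pearson correlation weights are
    computed, a series of progressively thresholded networks is generated
    (absolute or signed thresholding), each protein is scored on every member
    network with a base centrality measure (degree, betweenness, closeness,
    eigenvector or subgraph centrality), per-network scores are
    max-normalized, and a weighted vote combines them into a final
    essentiality ranking. Includes the PCC-threshold and PCC-weighted
    single-network baselines, an evaluation battery (top-n essential counts,
    ranking overlaps, low-degree analysis, node-strength and co-expression
    weight distributions) and a seeded synthetic benchmark generator with
    planted co-expressed essential modules and decoy hubs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    igraph,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
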