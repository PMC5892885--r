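Package: ognet
Title: Essential Protein Prediction from Interaction Networks, Co-Expression, and Orthology
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Ranks proteins in a protein-protein interaction network by their
    likelihood of being essential using the OGN centrality measure, an
    alpha-weighted blend of a max-normalized orthology conservation score and a
    co-expression-weighted sum of neighbour clustering coefficients. Includes
    the standard topology-only baselines (degree, betweenness, closeness,
    eigenvector, and subgraph centrality), a majority-voting ensemble over a
    grid of alpha values, the top-n / Jackknife / precision-recall evaluation
    protocol, a seeded synthetic-data generator with planted essential modules,
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    optparse,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
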