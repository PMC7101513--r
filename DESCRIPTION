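Package: ppiscreen
Title: Hub-Bottleneck Screening and Action-Network Analysis of
    Protein-Protein Interaction Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A reusable pipeline for interactomic screening of disease gene
    sets. Reads STRING-style protein-protein interaction edge lists, extracts
    the main connected component, computes degree and normalized betweenness
    centrality (Brandes' algorithm), fits the degree distribution to a power
    law y = a*x^b by log-log least squares, classifies nodes as hubs (degree
    above mean + SD), bottlenecks (top 5% by betweenness) and hub-bottlenecks,
    induces and re-ranks the central-gene sub-network, and analyses typed
    directed action networks (expression with up/down sign, activation,
    inhibition): layer participation, per-gene regulatory tallies, weakly
    connected inhibition components and reciprocal pairs. Ships a seeded
    scale-free synthetic-network generator with plantable action facts so the
    whole pipeline is testable without any database download.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    graphics,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
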