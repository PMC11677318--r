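Package: amylonet
Title: Heterogeneous Disease-Protein-Drug Network Analysis for Amyloidoses
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Builds and analyses heterogeneous tripartite networks linking
    amyloid-associated diseases, amyloidogenic and co-deposited proteins,
    and drugs. Ingests disease-protein association tables, confidence-scored
    protein-protein interactions, drug-target and drug-indication tables
    under explicit filtering rules (score threshold, neighbor cap, organism
    and metal-compound exclusion); characterises the assembled network
    (density, clustering, path length, heterogeneity, power-law degree fit,
    Erdos-Renyi null comparison); projects it onto a weighted disease-disease
    network via shared first neighbors with dense-group discovery; and ranks
    drug-repurposing candidates by betweenness centrality. Ships a seeded
    synthetic-data generator with ground truth so the full pipeline is
    testable without database downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    Matrix,
    xml2,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
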