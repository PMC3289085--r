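Package: oiip
Title: Ontology-Weighted Protein Complex Detection in Protein Interaction Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects protein complexes in protein-protein interaction (PPI)
    networks by first converting the unweighted network into a weighted graph
    -- each edge carries a Gene Ontology (GO) annotation-based semantic
    similarity plus a shared-neighbour topology weight -- and then growing
    clusters greedily from high-weight seed vertices under an interaction
    probability threshold and a diameter bound (the OIIP algorithm). Includes
    readers for OBO ontologies, GAF 2.x annotation files, edge lists and
    benchmark complex catalogues; evaluation of predictions by neighbourhood
    affinity matching (precision/recall/F-measure), clustering-wise
    sensitivity/PPV/accuracy, and hypergeometric functional homogeneity; and a
    seeded generator of fully synthetic toy inputs with planted complexes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils
Suggests:
    igraph,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
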