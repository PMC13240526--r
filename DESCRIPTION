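Package: ccnnet
Title: Cross-Species Seed-Gene-Centered Co-Expression and PPI Network Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis pipeline for characterizing the regulatory
    neighborhood of matricellular seed genes (the CCN family) during
    chondrogenic differentiation across species. Detects co-expression
    modules with a signed-hybrid adjacency and topological overlap, builds
    first-neighbor protein-protein interaction subnetworks around seed
    genes, quantifies module and network stability under resampling, scores
    ortholog-based cross-species conservation, performs over-representation
    analysis with functional-category rollup, and scores gene-set activity
    and ligand-receptor interaction strength in single-cell data. Ships a
    synthetic-data generator with planted ground truth so the whole pipeline
    is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    Matrix,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
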