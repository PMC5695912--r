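Package: coRewire
Title: Differential Co-Expression Network Analysis for Paired Two-Condition Studies
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects rewiring of gene co-expression networks between two
    paired conditions (for example skeletal muscle before and after a
    period of endurance training) and ranks candidate regulator genes.
    Implements a modified DiffCoEx workflow: differential adjacency from
    the change in pairwise correlation, topological-overlap module
    detection, a paired-permutation filter on gene-pair correlation
    changes, and a size-matched random-cluster null for module-module
    dispersion. Companion tools cover paired SAM-style differential
    expression, hypergeometric and ranked (GSEA-style) gene-set
    enrichment, a regulator-pathway-phenotype integration graph with
    degree ranking, condition-specific seed-gene networks, Voronoi
    capillary-domain morphometry, and a synthetic-data generator with
    planted ground truth for validating every stage.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    igraph,
    limma,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
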