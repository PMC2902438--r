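Package: icemod
Title: Co-Expression Modules by Iterative Clique Enumeration
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Builds thresholded gene co-expression networks from expression
    matrices, guides correlation-threshold selection with Gene Ontology
    (Resnik) semantic similarity, extracts relatively independent maximal
    cliques as co-expression modules by iterative clique enumeration with an
    exact branch-and-bound maximum-clique search, screens module overall
    expression for monotone association with an ordered phenotype (e.g.
    tumor grade) using the Jonckheere-Terpstra trend test with
    Benjamini-Hochberg correction, tests module over-representation against
    gene-set collections (GMT) with the hypergeometric test, quantifies
    cross-cohort reproducibility of module biomarkers, and simulates
    expression data with planted co-expressed, trend-bearing modules for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    fgsea
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
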