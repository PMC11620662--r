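Package: orthoconverge
Title: Comparative Gill Transcriptomics Across Freshwater-Saltwater Ecotype Pairs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparative bulk RNA-seq analysis of freshwater versus
    saltwater ecotype pairs sampled from multiple fish lineages. Implements
    TMM normalization, negative binomial GLM differential expression with
    empirical-Bayes tagwise dispersion and likelihood-ratio tests,
    orthogroup-level count aggregation with directional cross-lineage
    intersection analysis of convergent expression, weighted gene
    co-expression network analysis (soft thresholding, topological overlap,
    module eigengenes, module-trait correlation), hypergeometric GO
    over-representation, classical multidimensional scaling, and a seeded
    multi-lineage negative binomial count simulator with planted effects for
    end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    ape
Suggests:
    testthat (>= 3.0.0),
    withr,
    edgeR,
    mclust,
    vegan,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
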