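Package: mpanet
Title: Multipartite Association Networks from Bulk Transcriptomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Builds a queryable multipartite association network from bulk
    transcriptomics and phenotype data. Independent analytic layers
    (quantile normalization and probe filtering, factorial moderated-t
    differential expression, weighted co-expression module discovery with
    topological overlap, pre-defined transcriptional module scoring,
    cell-type deconvolution by non-negative least squares, hypergeometric
    gene-set enrichment, and phenotype association) are each enumerated as
    typed bipartite graphs and merged, by node identity, into one property
    graph supporting path-pattern queries with property predicates and
    export to GraphML, node/edge tables, or Cypher scripts. Includes a
    synthetic-data generator with planted co-expression modules, a known
    cell-mixture structure and a two-factor phenotype design so the whole
    pipeline is testable against ground truth, plus virtual-cell and
    meta-analysis summaries on top of the merged network.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    limma,
    igraph,
    pracma,
    yaml,
    jsonlite,
    data.table,
    SummarizedExperiment,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    fgsea
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
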