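#' @import methods
#' @importFrom stats cor cor.test median p.adjust phyper pt quantile sd var
#'   fisher.test kruskal.test wilcox.test prcomp hclust cutree as.dist
#'   model.matrix rnorm runif setNames complete.cases dist aggregate
#' @importFrom utils head read.delim write.table combn modifyList
NULL

## Admissible node labels and edge types of the multipartite association
## network. Exactly these twelve labels and three edge types may appear.
NODE_LABELS <- c("PROBETYPE", "PROBE", "SYMBOL", "wgcna", "baylor",
                 "reactomePW", "PalWangPW", "ImmunePW", "cellEx", "CELL",
                 "cellprop", "pheno")
EDGE_TYPES <- c("correlation", "enrichment", "mapping")

## Field separator inside node identity keys; forbidden in identity fields.
.KEY_SEP <- "\x1f"

#' Typed multipartite property graph
#'
#' Container for the merged association network. Nodes are identified by the
#' quadruple (label, name, square, edge): `label` is the node class (one of
#' the twelve admissible labels), `name` the identifier, `square` the dataset
#' id ("" for global annotation nodes) and `edge` the contrast id ("" when
#' not contrast-scoped). Edges carry a type (`correlation`, `enrichment` or
#' `mapping`), the index of the bipartite graph they were enumerated from,
#' and an open property map (weight, p, q, ...).
#'
#' @slot nodes data.frame with columns `key`, `label`, `name`, `square`,
#'   `edge` and a list column `props` of named property lists.
#' @slot edges data.frame with columns `key`, `src`, `dst` (node keys),
#'   `type`, `graph_index` and a list column `props`.
#' @export
setClass("AssociationGraph",
         representation(nodes = "data.frame", edges = "data.frame"))

setValidity("AssociationGraph", function(object) {
  n <- object@nodes
  e <- object@edges
  msgs <- character(0)
  need_n <- c("key", "label", "name", "square", "edge", "props")
  need_e <- c("key", "src", "dst", "type", "graph_index", "props")
  if (!all(need_n %in% names(n))) {
    msgs <- c(msgs, "nodes must have columns key, label, name, square, edge, props")
  } else {
    if (anyDuplicated(n$key)) msgs <- c(msgs, "duplicate node keys")
    bad <- setdiff(unique(n$label), NODE_LABELS)
    if (length(bad))
      msgs <- c(msgs, paste0("unknown node label(s): ", paste(bad, collapse = ", ")))
    if (nrow(n) && any(grepl(.KEY_SEP, paste(n$name, n$square, n$edge), fixed = TRUE)))
      msgs <- c(msgs, "identity fields may not contain the key separator")
  }
  if (!all(need_e %in% names(e))) {
    msgs <- c(msgs, "edges must have columns key, src, dst, type, graph_index, props")
  } else {
    if (anyDuplicated(e$key)) msgs <- c(msgs, "duplicate edge keys")
    bad <- setdiff(unique(e$type), EDGE_TYPES)
    if (length(bad))
      msgs <- c(msgs, paste0("unknown edge type(s): ", paste(bad, collapse = ", ")))
    if (nrow(e) && !all(c(e$src, e$dst) %in% n$key))
      msgs <- c(msgs, "edge endpoints must exist as nodes")
  }
  if (length(msgs)) msgs else TRUE
})

#' @describeIn AssociationGraph compact summary
#' @param object an `AssociationGraph`
#' @export
setMethod("show", "AssociationGraph", function(object) {
  cat("AssociationGraph with", nrow(object@nodes), "nodes and",
      nrow(object@edges), "edges\n")
  if (nrow(object@nodes)) {
    tab <- table(object@nodes$label)
    cat("  node labels:",
        paste(sprintf("%s(%d)", names(tab), as.integer(tab)), collapse = " "),
        "\n")
  }
  if (nrow(object@edges)) {
    tab <- table(object@edges$type)
    cat("  edge types: ",
        paste(sprintf("%s(%d)", names(tab), as.integer(tab)), collapse = " "),
        "\n")
    gi <- sort(unique(object@edges$graph_index))
    cat("  graph indices:", paste(gi, collapse = " "), "\n")
  }
  invisible(object)
})

#' Annotation bundle
#'
#' Holds the prior-knowledge inputs of a network build: the probe-to-symbol
#' map, three pathway collections, three cell-marker collections, the
#' pre-defined transcriptional module definitions, the deconvolution
#' signature basis, and the map from collection-specific cell labels to
#' consensus cell names.
#'
#' @slot probe2symbol named character vector, probe id -> gene symbol.
#' @slot pathwayCollections named list (three collections) of named lists of
#'   symbol vectors.
#' @slot markerCollections named list (three collections) of named lists of
#'   symbol vectors; list names are collection-specific cell labels.
#' @slot predefinedModules named list of symbol vectors (fixed module
#'   definitions reused across datasets).
#' @slot basis numeric matrix, marker probes x cell types, linear scale.
#' @slot cellNameMap named character vector mapping every cell label used in
#'   `markerCollections` and `basis` columns to a consensus CELL name.
#' @export
setClass("AnnotationBundle",
         representation(probe2symbol = "character",
                        pathwayCollections = "list",
                        markerCollections = "list",
                        predefinedModules = "list",
                        basis = "matrix",
                        cellNameMap = "character"))

setValidity("AnnotationBundle", function(object) {
  msgs <- character(0)
  if (length(object@probe2symbol) && is.null(names(object@probe2symbol)))
    msgs <- c(msgs, "probe2symbol must be named by probe id")
  for (coll in object@markerCollections)
    if (length(coll) && !all(names(coll) %in% names(object@cellNameMap)))
      msgs <- c(msgs, "cellNameMap must cover every marker collection cell label")
  if (ncol(object@basis) &&
      !all(colnames(object@basis) %in% names(object@cellNameMap)))
    msgs <- c(msgs, "cellNameMap must cover every basis cell label")
  if (length(msgs)) unique(msgs) else TRUE
})

#' @describeIn AnnotationBundle compact summary
#' @param object an `AnnotationBundle`
#' @export
setMethod("show", "AnnotationBundle", function(object) {
  cat("AnnotationBundle:",
      length(object@probe2symbol), "probe->symbol mappings;",
      length(object@pathwayCollections), "pathway collections;",
      length(object@markerCollections), "marker collections;",
      length(object@predefinedModules), "pre-defined modules;",
      "basis", nrow(object@basis), "x", ncol(object@basis), "\n")
  invisible(object)
})
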