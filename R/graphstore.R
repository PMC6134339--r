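## In-process property graph with MERGE semantics, graph union, path-pattern
## matching with property predicates, and deterministic exporters.

#' Build a node identity key
#'
#' Node identity is the quadruple (label, name, square, edge); two nodes with
#' the same label and name but different dataset (`square`) or contrast
#' (`edge`) scope are distinct.
#'
#' @param label,name,square,edge character vectors (recycled).
#' @return character vector of keys.
#' @export
nodeKey <- function(label, name, square = "", edge = "") {
  paste(label, name, square, edge, sep = .KEY_SEP)
}

.parseKey <- function(keys) {
  parts <- strsplit(keys, .KEY_SEP, fixed = TRUE)
  data.frame(label = vapply(parts, `[`, "", 1),
             name = vapply(parts, `[`, "", 2),
             square = vapply(parts, function(p) if (length(p) >= 3) p[3] else "", ""),
             edge = vapply(parts, function(p) if (length(p) >= 4) p[4] else "", ""),
             stringsAsFactors = FALSE)
}

.edgeKey <- function(src, dst, type, graph_index) {
  paste(src, dst, type, graph_index, sep = .KEY_SEP)
}

## property values are scalars; logicals are normalised to 0/1 so every
## exporter round-trips them identically
.normProps <- function(props) {
  stopifnot(is.list(props))
  lapply(props, function(v) {
    if (is.logical(v)) as.numeric(v) else v
  })
}

.emptyNodes <- function() {
  data.frame(key = character(0), label = character(0), name = character(0),
             square = character(0), edge = character(0),
             props = I(list()), stringsAsFactors = FALSE)
}

.emptyEdges <- function() {
  data.frame(key = character(0), src = character(0), dst = character(0),
             type = character(0), graph_index = numeric(0),
             props = I(list()), stringsAsFactors = FALSE)
}

#' Create an empty association graph
#' @return an [AssociationGraph-class] with no nodes or edges.
#' @export
emptyGraph <- function() {
  new("AssociationGraph", nodes = .emptyNodes(), edges = .emptyEdges())
}

#' @rdname graphAccessors
#' @export
setGeneric("graphNodes", function(graph) standardGeneric("graphNodes"))

#' @rdname graphAccessors
#' @export
setGeneric("graphEdges", function(graph) standardGeneric("graphEdges"))

#' Accessors for association graphs
#'
#' `graphNodes()` and `graphEdges()` return the node and edge tables
#' (including the `props` list column); `nodeCount()`/`edgeCount()` the
#' respective sizes.
#'
#' @param graph an [AssociationGraph-class].
#' @return a data.frame (tables) or integer (counts).
#' @name graphAccessors
NULL

#' @rdname graphAccessors
#' @export
setMethod("graphNodes", "AssociationGraph", function(graph) graph@nodes)

#' @rdname graphAccessors
#' @export
setMethod("graphEdges", "AssociationGraph", function(graph) graph@edges)

#' @rdname graphAccessors
#' @export
nodeCount <- function(graph) nrow(graph@nodes)

#' @rdname graphAccessors
#' @export
edgeCount <- function(graph) nrow(graph@edges)

#' Retrieve a node's property map
#' @param graph an [AssociationGraph-class].
#' @param key node key as produced by [nodeKey()].
#' @return named list of properties (empty list if node absent).
#' @export
nodeProps <- function(graph, key) {
  i <- match(key, graph@nodes$key)
  if (is.na(i)) list() else graph@nodes$props[[i]]
}

#' Merge a node into a graph (idempotent)
#'
#' If a node with the same identity key exists, its property map is overlaid
#' with `props` (new values win, untouched properties kept) and the node
#' count is unchanged; otherwise the node is inserted.
#'
#' @param graph an [AssociationGraph-class].
#' @param label node label, one of the twelve admissible labels.
#' @param name,square,edge identity fields.
#' @param props named list of scalar properties.
#' @return the updated graph.
#' @export
mergeNode <- function(graph, label, name, square = "", edge = "",
                      props = list()) {
  if (!label %in% NODE_LABELS)
    stop("unknown node label: ", label)
  key <- nodeKey(label, name, square, edge)
  props <- .normProps(props)
  i <- match(key, graph@nodes$key)
  if (is.na(i)) {
    graph@nodes <- rbind(graph@nodes, data.frame(
      key = key, label = label, name = name, square = square, edge = edge,
      props = I(list(props)), stringsAsFactors = FALSE))
  } else {
    graph@nodes$props[[i]] <- utils::modifyList(graph@nodes$props[[i]], props)
  }
  graph
}

#' Merge an edge into a graph (idempotent)
#'
#' Edge identity is (source, target, type, graph_index); re-merging the same
#' edge overlays its properties. Missing endpoint nodes are created
#' implicitly from their keys (MERGE semantics).
#'
#' @param graph an [AssociationGraph-class].
#' @param src,dst node keys ([nodeKey()]).
#' @param type edge type: "correlation", "enrichment" or "mapping".
#' @param graph_index index of the bipartite graph this edge belongs to.
#' @param props named list of scalar properties (weight, p, q, ...).
#' @return the updated graph.
#' @export
mergeEdge <- function(graph, src, dst, type, graph_index = NA_real_,
                      props = list()) {
  if (!type %in% EDGE_TYPES)
    stop("unknown edge type: ", type)
  for (k in c(src, dst)) {
    if (!k %in% graph@nodes$key) {
      f <- .parseKey(k)
      graph <- mergeNode(graph, f$label, f$name, f$square, f$edge)
    }
  }
  props <- .normProps(props)
  key <- .edgeKey(src, dst, type, graph_index)
  i <- match(key, graph@edges$key)
  if (is.na(i)) {
    graph@edges <- rbind(graph@edges, data.frame(
      key = key, src = src, dst = dst, type = type,
      graph_index = as.numeric(graph_index),
      props = I(list(props)), stringsAsFactors = FALSE))
  } else {
    graph@edges$props[[i]] <- utils::modifyList(graph@edges$props[[i]], props)
  }
  graph
}

## Bulk constructor used by the pipeline: nodes/edges as data.frames with a
## props list column; duplicates within the input are merged left-to-right.
.bulkGraph <- function(nodes = NULL, edges = NULL) {
  g <- emptyGraph()
  if (!is.null(nodes) && nrow(nodes)) {
    nodes$key <- nodeKey(nodes$label, nodes$name, nodes$square, nodes$edge)
    if (is.null(nodes$props)) nodes$props <- I(rep(list(list()), nrow(nodes)))
    nodes$props <- lapply(nodes$props, .normProps)
    if (anyDuplicated(nodes$key)) {
      sp <- split(seq_len(nrow(nodes)), nodes$key)
      keep <- vapply(sp, `[`, 0L, 1L)
      for (idx in sp[lengths(sp) > 1]) {
        acc <- nodes$props[[idx[1]]]
        for (j in idx[-1]) acc <- utils::modifyList(acc, nodes$props[[j]])
        nodes$props[[idx[1]]] <- acc
      }
      nodes <- nodes[sort(keep), , drop = FALSE]
    }
    g@nodes <- data.frame(key = nodes$key, label = nodes$label,
                          name = nodes$name, square = nodes$square,
                          edge = nodes$edge, props = I(nodes$props),
                          stringsAsFactors = FALSE)
  }
  if (!is.null(edges) && nrow(edges)) {
    if (is.null(edges$props)) edges$props <- I(rep(list(list()), nrow(edges)))
    edges$props <- lapply(edges$props, .normProps)
    edges$key <- .edgeKey(edges$src, edges$dst, edges$type, edges$graph_index)
    edges <- edges[!duplicated(edges$key), , drop = FALSE]
    missing <- setdiff(unique(c(edges$src, edges$dst)), g@nodes$key)
    if (length(missing)) {
      f <- .parseKey(missing)
      g@nodes <- rbind(g@nodes, data.frame(
        key = missing, label = f$label, name = f$name, square = f$square,
        edge = f$edge, props = I(rep(list(list()), length(missing))),
        stringsAsFactors = FALSE))
    }
    g@edges <- data.frame(key = edges$key, src = edges$src, dst = edges$dst,
                          type = edges$type,
                          graph_index = as.numeric(edges$graph_index),
                          props = I(edges$props), stringsAsFactors = FALSE)
  }
  methods::validObject(g)
  g
}

#' Union of association graphs
#'
#' Folds MERGE over all nodes and edges of the inputs: shared identity keys
#' appear once with properties overlaid left to right. The operation is
#' associative and idempotent on keys.
#'
#' @param graphs list of [AssociationGraph-class] objects (or several graphs
#'   as `...`).
#' @param ... graphs, if `graphs` is not a list.
#' @return the merged [AssociationGraph-class].
#' @export
graphUnion <- function(graphs, ...) {
  if (is(graphs, "AssociationGraph")) graphs <- c(list(graphs), list(...))
  stopifnot(all(vapply(graphs, is, TRUE, "AssociationGraph")))
  nodes <- do.call(rbind, lapply(graphs, function(g) g@nodes))
  edges <- do.call(rbind, lapply(graphs, function(g) g@edges))
  g <- emptyGraph()
  if (!is.null(nodes) && nrow(nodes)) {
    if (anyDuplicated(nodes$key)) {
      sp <- split(seq_len(nrow(nodes)), nodes$key)
      keep <- sort(vapply(sp, `[`, 0L, 1L))
      for (idx in sp[lengths(sp) > 1]) {
        acc <- nodes$props[[idx[1]]]
        for (j in idx[-1]) acc <- utils::modifyList(acc, nodes$props[[j]])
        nodes$props[[idx[1]]] <- acc
      }
      nodes <- nodes[keep, , drop = FALSE]
    }
    g@nodes <- nodes
  }
  if (!is.null(edges) && nrow(edges)) {
    if (anyDuplicated(edges$key)) {
      sp <- split(seq_len(nrow(edges)), edges$key)
      keep <- sort(vapply(sp, `[`, 0L, 1L))
      for (idx in sp[lengths(sp) > 1]) {
        acc <- edges$props[[idx[1]]]
        for (j in idx[-1]) acc <- utils::modifyList(acc, edges$props[[j]])
        edges$props[[idx[1]]] <- acc
      }
      edges <- edges[keep, , drop = FALSE]
    }
    g@edges <- edges
  }
  rownames(g@nodes) <- NULL
  rownames(g@edges) <- NULL
  g
}

## ---------------------------------------------------------------------------
## Pattern queries

#' Construct a path-pattern query
#'
#' A pattern is an alternating sequence of node constraints and edge
#' constraints, matched undirected against the graph, in the spirit of a
#' Cypher `MATCH ... WHERE ...` path query. Each node constraint is a list
#' with `label` and optional `preds`; each edge constraint a list with
#' optional `type` and `preds`. A predicate is `list(prop, op, value)` with
#' `op` one of `=`, `!=`, `>`, `<`, `>=`, `<=`. Candidates lacking the
#' referenced property fail the predicate.
#'
#' @param nodes list of node constraints.
#' @param edges list of edge constraints (length `length(nodes) - 1`).
#' @return a `PatternQuery` (plain list with class attribute).
#' @export
patternQuery <- function(nodes, edges = NULL) {
  if (is.null(edges)) edges <- rep(list(list()), max(0, length(nodes) - 1))
  stopifnot(length(nodes) >= 1, length(edges) == length(nodes) - 1)
  structure(list(nodes = nodes, edges = edges), class = "PatternQuery")
}

#' Parse a compact pattern string
#'
#' Accepts a compact textual form of a path pattern, e.g.
#' `"(pheno)-[weight>0.6]-(wgcna{square='d1'})-[]-(PROBE{logfc>2})-[]-(SYMBOL)"`.
#' Node constraints are `(label{prop op value, ...})`; edge constraints are
#' `[type: prop op value, ...]` where both the type and the predicate list
#' are optional. String values are quoted with `'`.
#'
#' @param text pattern string.
#' @return a `PatternQuery`.
#' @export
parsePattern <- function(text) {
  nodeRaw <- regmatches(text, gregexpr("\\(([^()]*)\\)", text))[[1]]
  edgeRaw <- regmatches(text, gregexpr("\\[([^][]*)\\]", text))[[1]]
  if (!length(nodeRaw)) stop("pattern contains no node constraints")
  parsePreds <- function(s) {
    s <- trimws(s)
    if (!nzchar(s)) return(list())
    out <- list()
    for (cond in strsplit(s, ",", fixed = TRUE)[[1]]) {
      m <- regexec("^\\s*([A-Za-z_][A-Za-z0-9_.]*)\\s*(>=|<=|!=|=|>|<)\\s*(.+?)\\s*$",
                   cond)[[1]]
      if (m[1] == -1) stop("cannot parse predicate: ", cond)
      parts <- regmatches(cond, regexec(
        "^\\s*([A-Za-z_][A-Za-z0-9_.]*)\\s*(>=|<=|!=|=|>|<)\\s*(.+?)\\s*$", cond))[[1]]
      val <- parts[4]
      if (grepl("^'.*'$", val)) val <- substr(val, 2, nchar(val) - 1)
      else {
        num <- suppressWarnings(as.numeric(val))
        if (!is.na(num)) val <- num
      }
      out[[length(out) + 1]] <- list(prop = parts[2], op = parts[3], value = val)
    }
    out
  }
  nodes <- lapply(nodeRaw, function(s) {
    s <- substr(s, 2, nchar(s) - 1)
    m <- regmatches(s, regexec("^\\s*([A-Za-z]+)\\s*(\\{(.*)\\})?\\s*$", s))[[1]]
    if (!length(m)) stop("cannot parse node constraint: ", s)
    list(label = m[2], preds = parsePreds(m[4]))
  })
  edges <- lapply(edgeRaw, function(s) {
    s <- substr(s, 2, nchar(s) - 1)
    type <- NULL
    if (grepl(":", s, fixed = TRUE)) {
      bits <- strsplit(s, ":", fixed = TRUE)[[1]]
      type <- trimws(bits[1])
      s <- paste(bits[-1], collapse = ":")
    }
    list(type = type, preds = parsePreds(s))
  })
  if (length(edges) != length(nodes) - 1)
    edges <- rep(list(list()), length(nodes) - 1)
  patternQuery(nodes, edges)
}

.checkPreds <- function(props, preds, missingSeen) {
  for (pr in preds) {
    v <- props[[pr$prop]]
    if (is.null(v) || is.na(v)) {
      if (!pr$prop %in% missingSeen$props) {
        message("predicate on missing property '", pr$prop,
                "' fails for some candidates")
        missingSeen$props <- c(missingSeen$props, pr$prop)
      }
      return(FALSE)
    }
    ok <- switch(pr$op,
                 "=" = v == pr$value, "==" = v == pr$value,
                 "!=" = v != pr$value,
                 ">" = v > pr$value, "<" = v < pr$value,
                 ">=" = v >= pr$value, "<=" = v <= pr$value,
                 stop("unknown operator: ", pr$op))
    if (!isTRUE(ok)) return(FALSE)
  }
  TRUE
}

#' Match a path pattern against a graph
#'
#' Enumerates every simple path (no repeated node) whose node labels, edge
#' types and property predicates satisfy the query. Matching is undirected.
#' Paths are returned in deterministic lexicographic order of their node
#' keys.
#'
#' @param graph an [AssociationGraph-class].
#' @param query a `PatternQuery` ([patternQuery()] / [parsePattern()]) or a
#'   pattern string.
#' @return list with `paths` (list of character vectors of node keys),
#'   `edgeKeys` (matching edge keys per path) and `subgraph` (an
#'   [AssociationGraph-class], the union of all matched paths).
#' @export
matchPattern <- function(graph, query) {
  if (is.character(query)) query <- parsePattern(query)
  stopifnot(inherits(query, "PatternQuery"))
  nq <- length(query$nodes)
  nodes <- graph@nodes
  edges <- graph@edges
  missingSeen <- new.env()
  missingSeen$props <- character(0)

  nodeOk <- function(i, cons) {
    nodes$label[i] == cons$label &&
      .checkPreds(nodes$props[[i]], cons$preds %||% list(), missingSeen)
  }
  candidates <- lapply(query$nodes, function(cons) {
    idx <- which(nodes$label == cons$label)
    idx[vapply(idx, function(i)
      .checkPreds(nodes$props[[i]], cons$preds %||% list(), missingSeen), TRUE)]
  })

  ## undirected incidence: for each node key, rows of the edge table
  inc <- split(rep(seq_len(nrow(edges)), 2L), c(edges$src, edges$dst))

  paths <- list()
  pathEdges <- list()
  extend <- function(nodeIdx, edgeIdx, depth) {
    if (depth == nq) {
      paths[[length(paths) + 1]] <<- nodes$key[nodeIdx]
      pathEdges[[length(pathEdges) + 1]] <<- edges$key[edgeIdx]
      return(invisible())
    }
    cur <- nodes$key[nodeIdx[depth]]
    cons <- query$edges[[depth]]
    nextCons <- query$nodes[[depth + 1]]
    for (ei in inc[[cur]]) {
      if (!is.null(cons$type) && edges$type[ei] != cons$type) next
      if (!.checkPreds(edges$props[[ei]], cons$preds %||% list(), missingSeen)) next
      other <- if (edges$src[ei] == cur) edges$dst[ei] else edges$src[ei]
      oi <- match(other, nodes$key)
      if (oi %in% nodeIdx) next               # simple paths only
      if (!oi %in% candidates[[depth + 1]]) next
      extend(c(nodeIdx, oi), c(edgeIdx, ei), depth + 1)
    }
  }
  for (s in candidates[[1]]) extend(s, integer(0), 1)

  if (length(paths)) {
    ord <- order(vapply(paths, function(p) paste(p, collapse = .KEY_SEP), ""))
    paths <- paths[ord]
    pathEdges <- pathEdges[ord]
  }
  usedNodes <- unique(unlist(paths))
  usedEdges <- unique(unlist(pathEdges))
  sub <- emptyGraph()
  if (length(usedNodes)) {
    sub@nodes <- nodes[match(sort(usedNodes), nodes$key), , drop = FALSE]
    rownames(sub@nodes) <- NULL
  }
  if (length(usedEdges)) {
    sub@edges <- edges[match(sort(usedEdges), edges$key), , drop = FALSE]
    rownames(sub@edges) <- NULL
  }
  list(paths = paths, edgeKeys = pathEdges, subgraph = sub)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## ---------------------------------------------------------------------------
## Exporters

.propUnion <- function(propList) {
  sort(unique(unlist(lapply(propList, names))))
}

.propColumns <- function(propList, propNames) {
  out <- list()
  for (p in propNames) {
    vals <- lapply(propList, function(pr) pr[[p]])
    isNum <- all(vapply(vals, function(v) is.null(v) || is.numeric(v), TRUE))
    if (isNum) {
      out[[p]] <- vapply(vals, function(v) if (is.null(v)) NA_real_ else as.numeric(v), 0)
    } else {
      out[[p]] <- vapply(vals, function(v) if (is.null(v)) NA_character_ else as.character(v), "")
    }
  }
  out
}

.fmtNum <- function(x) {
  vapply(x, function(v) {
    if (is.na(v)) "null" else formatC(v, digits = 15, format = "g")
  }, "")
}

#' Export an association graph
#'
#' @param graph an [AssociationGraph-class].
#' @param format `"graphml"` (single file, via igraph), `"tsv_pair"`
#'   (`<file>.nodes.tsv` and `<file>.edges.tsv`, Cytoscape-ready) or
#'   `"cypher"` (a deterministic script of MERGE statements, nodes before
#'   edges, sorted by identity key; byte-identical across runs on the same
#'   graph).
#' @param file output path (for `tsv_pair`, the common prefix).
#' @return invisibly, the path(s) written.
#' @export
exportGraph <- function(graph, format = c("graphml", "tsv_pair", "cypher"),
                        file) {
  format <- match.arg(format)
  nodes <- graph@nodes[order(graph@nodes$key), , drop = FALSE]
  edges <- graph@edges[order(graph@edges$key), , drop = FALSE]
  switch(format,
    graphml = {
      np <- .propColumns(nodes$props, .propUnion(nodes$props))
      ## vertex ids are positional: identity keys contain a control character
      ## that XML cannot carry; keys are rebuilt from attributes on import
      vid <- paste0("v", seq_len(nrow(nodes)))
      vdf <- data.frame(name = vid, label = nodes$label,
                        node_name = nodes$name, square = nodes$square,
                        edge_scope = nodes$edge, stringsAsFactors = FALSE)
      for (p in names(np)) vdf[[paste0("p_", p)]] <- np[[p]]
      ep <- .propColumns(edges$props, .propUnion(edges$props))
      edf <- data.frame(from = vid[match(edges$src, nodes$key)],
                        to = vid[match(edges$dst, nodes$key)],
                        type = edges$type,
                        graph_index = edges$graph_index,
                        stringsAsFactors = FALSE)
      for (p in names(ep)) edf[[paste0("p_", p)]] <- ep[[p]]
      ig <- igraph::graph_from_data_frame(edf, directed = FALSE, vertices = vdf)
      igraph::write_graph(ig, file, format = "graphml")
      invisible(file)
    },
    tsv_pair = {
      nFile <- paste0(file, ".nodes.tsv")
      eFile <- paste0(file, ".edges.tsv")
      np <- .propColumns(nodes$props, .propUnion(nodes$props))
      ndf <- data.frame(label = nodes$label, name = nodes$name,
                        square = nodes$square, edge = nodes$edge,
                        stringsAsFactors = FALSE)
      for (p in names(np)) ndf[[p]] <- np[[p]]
      sf <- .parseKey(edges$src); df <- .parseKey(edges$dst)
      ep <- .propColumns(edges$props, .propUnion(edges$props))
      edf <- data.frame(src_label = sf$label, src_name = sf$name,
                        src_square = sf$square, src_edge = sf$edge,
                        dst_label = df$label, dst_name = df$name,
                        dst_square = df$square, dst_edge = df$edge,
                        type = edges$type, graph_index = edges$graph_index,
                        stringsAsFactors = FALSE)
      for (p in names(ep)) edf[[p]] <- ep[[p]]
      utils::write.table(ndf, nFile, sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(edf, eFile, sep = "\t", quote = FALSE, row.names = FALSE)
      invisible(c(nFile, eFile))
    },
    cypher = {
      esc <- function(s) gsub("'", "\\\\'", s)
      fmtProp <- function(k, v) {
        if (is.numeric(v)) sprintf("%s: %s", k, .fmtNum(v))
        else sprintf("%s: '%s'", k, esc(as.character(v)))
      }
      propStr <- function(pr) {
        if (!length(pr)) return("")
        pr <- pr[order(names(pr))]
        paste0(", ", paste(mapply(fmtProp, names(pr), pr), collapse = ", "))
      }
      lines <- character(0)
      for (i in seq_len(nrow(nodes))) {
        lines <- c(lines, sprintf(
          "MERGE (n:%s {name: '%s', square: '%s', edge: '%s'}) SET n += {dummy: 0%s};",
          nodes$label[i], esc(nodes$name[i]), esc(nodes$square[i]),
          esc(nodes$edge[i]), propStr(nodes$props[[i]])))
      }
      for (i in seq_len(nrow(edges))) {
        s <- .parseKey(edges$src[i]); d <- .parseKey(edges$dst[i])
        lines <- c(lines, sprintf(
          paste0("MATCH (a:%s {name: '%s', square: '%s', edge: '%s'}), ",
                 "(b:%s {name: '%s', square: '%s', edge: '%s'}) ",
                 "MERGE (a)-[r:%s {graph_index: %s}]->(b) ",
                 "SET r += {dummy: 0%s};"),
          s$label, esc(s$name), esc(s$square), esc(s$edge),
          d$label, esc(d$name), esc(d$square), esc(d$edge),
          edges$type[i], .fmtNum(edges$graph_index[i]),
          propStr(edges$props[[i]])))
      }
      writeLines(lines, file)
      invisible(file)
    })
}

#' Re-import a GraphML export
#'
#' Inverse of `exportGraph(..., "graphml")`: reconstructs the
#' [AssociationGraph-class] with identical identity keys and property maps
#' (properties absent on a node/edge stay absent).
#'
#' @param file path to a GraphML file written by [exportGraph()].
#' @return an [AssociationGraph-class].
#' @export
importGraphML <- function(file) {
  ig <- igraph::read_graph(file, format = "graphml")
  va <- igraph::vertex_attr(ig)
  ea <- igraph::edge_attr(ig)
  n <- igraph::vcount(ig)
  propNames <- grep("^p_", names(va), value = TRUE)
  props <- lapply(seq_len(n), function(i) {
    pr <- list()
    for (p in propNames) {
      v <- va[[p]][i]
      if (!is.na(v)) pr[[sub("^p_", "", p)]] <- v
    }
    pr
  })
  nodes <- data.frame(label = va$label, name = va$node_name,
                      square = va$square %||% rep("", n),
                      edge = va$edge_scope %||% rep("", n),
                      props = I(props), stringsAsFactors = FALSE)
  ## igraph may read empty strings as NA
  nodes$square[is.na(nodes$square)] <- ""
  nodes$edge[is.na(nodes$edge)] <- ""
  nodes$key <- nodeKey(nodes$label, nodes$name, nodes$square, nodes$edge)
  m <- igraph::ecount(ig)
  el <- igraph::as_edgelist(ig, names = TRUE)
  epropNames <- grep("^p_", names(ea), value = TRUE)
  eprops <- lapply(seq_len(m), function(i) {
    pr <- list()
    for (p in epropNames) {
      v <- ea[[p]][i]
      if (!is.na(v)) pr[[sub("^p_", "", p)]] <- v
    }
    pr
  })
  keyMap <- setNames(nodes$key, va$name)
  edges <- data.frame(src = keyMap[el[, 1]], dst = keyMap[el[, 2]],
                      type = if (m) ea$type else character(0),
                      graph_index = if (m) as.numeric(ea$graph_index) else numeric(0),
                      props = I(eprops), stringsAsFactors = FALSE)
  edges$key <- .edgeKey(edges$src, edges$dst, edges$type, edges$graph_index)
  g <- emptyGraph()
  g@nodes <- nodes[, c("key", "label", "name", "square", "edge", "props")]
  g@edges <- edges[, c("key", "src", "dst", "type", "graph_index", "props")]
  rownames(g@nodes) <- NULL
  rownames(g@edges) <- NULL
  methods::validObject(g)
  g
}
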