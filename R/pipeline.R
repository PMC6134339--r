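## Orchestration: run every analytic layer per dataset, enumerate the 29
## bipartite graphs, union them into one association network, and report.

## Bipartite graph catalogue: index -> (node type 1, node type 2, edge type)
GRAPH_CATALOGUE <- data.frame(
  index = 1:29,
  type1 = c("PROBETYPE", "PROBE", "PROBE", "PROBE", "SYMBOL", "SYMBOL",
            "SYMBOL", "SYMBOL", "SYMBOL", "SYMBOL", "wgcna", "baylor",
            "baylor", "baylor", "wgcna", "wgcna", "wgcna", "baylor",
            "baylor", "baylor", "wgcna", "wgcna", "wgcna", "wgcna", "CELL",
            "CELL", "CELL", "CELL", "wgcna"),
  type2 = c("SYMBOL", "SYMBOL", "wgcna", "PROBE", "reactomePW", "PalWangPW",
            "ImmunePW", "cellEx", "cellEx", "cellEx", "baylor", "reactomePW",
            "PalWangPW", "ImmunePW", "reactomePW", "PalWangPW", "ImmunePW",
            "cellEx", "cellEx", "cellEx", "cellEx", "cellEx", "cellEx",
            "cellprop", "cellEx", "cellEx", "cellEx", "cellprop", "pheno"),
  type = c("mapping", "mapping", "mapping", "correlation", "mapping",
           "mapping", "mapping", "mapping", "mapping", "mapping",
           "enrichment", "enrichment", "enrichment", "enrichment",
           "enrichment", "enrichment", "enrichment", "enrichment",
           "enrichment", "enrichment", "enrichment", "enrichment",
           "enrichment", "correlation", "mapping", "mapping", "mapping",
           "mapping", "correlation"),
  stringsAsFactors = FALSE)

PATHWAY_LABELS <- c("reactomePW", "PalWangPW", "ImmunePW")

.defaultThresholds <- function() {
  list(q_cutoff = 0.05, p_cutoff = 0.05,
       min_keep = 3, max_keep = 10,
       ## per-collection minimum retention for pathway enrichment graphs
       ## (third collection: minimum of four)
       min_keep_pathway = c(3, 3, 4),
       edge_frac = 0.10, edge_cap = 2000,
       min_module_size = 30, merge_cor = 0.75,
       variance_q = 0.5, wgcna_filter = "variance",
       repertoire_q = 0.05)
}

#' Read a run configuration
#'
#' YAML schema: `project`, `seed`, optional `thresholds` (q_cutoff,
#' min_keep, max_keep, edge_frac, edge_cap, min_module_size, merge_cor,
#' variance_q, wgcna_filter), `datasets` (list of square, edge, expression,
#' pheno, class_var, strat_var, optional class_ref/strat_ref/id_vars/coef)
#' and `annotations` (probe2symbol, markers, pathways, predefined_modules,
#' basis, cellmap paths).
#'
#' @param path path to the YAML file.
#' @return validated config list (thresholds filled with defaults).
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$datasets) || !length(cfg$datasets))
    stop("config declares no datasets")
  squares <- vapply(cfg$datasets, function(d) d$square, "")
  if (anyDuplicated(squares)) stop("dataset ids (square) must be unique")
  for (d in cfg$datasets)
    for (f in c("expression", "pheno"))
      if (!file.exists(d[[f]])) stop("missing input file: ", d[[f]])
  cfg$thresholds <- utils::modifyList(.defaultThresholds(),
                                      cfg$thresholds %||% list())
  cfg$seed <- cfg$seed %||% 1
  cfg
}

.nodesDF <- function(label, name, square = "", edge = "", props = NULL) {
  n <- length(name)
  data.frame(label = label, name = name,
             square = rep(square, length.out = n),
             edge = rep(edge, length.out = n),
             props = I(props %||% rep(list(list()), n)),
             stringsAsFactors = FALSE)
}

.edgesDF <- function(src, dst, type, index, props = NULL) {
  n <- length(src)
  data.frame(src = src, dst = dst, type = type, graph_index = index,
             props = I(props %||% rep(list(list()), n)),
             stringsAsFactors = FALSE)
}

.rowProps <- function(df, cols) {
  lapply(seq_len(nrow(df)), function(i) {
    pr <- as.list(df[i, cols, drop = FALSE])
    pr[!vapply(pr, function(v) is.null(v) || (length(v) == 1 && is.na(v)), TRUE)]
  })
}

## enrichment results -> bipartite enrichment graph
.enrichGraph <- function(enr, index, leftLabel, leftSquare, leftEdge,
                         rightLabel) {
  keep <- enr[enr$retained, , drop = FALSE]
  if (!nrow(keep)) return(emptyGraph())
  .bulkGraph(edges = .edgesDF(
    nodeKey(leftLabel, keep$module, leftSquare, leftEdge),
    nodeKey(rightLabel, keep$set),
    "enrichment", index,
    props = .rowProps(keep, c("k", "n", "K", "N", "p", "q", "relaxed"))))
}

#' Run the full multi-dataset build
#'
#' For every dataset: ingestion and alignment, normalization, probe
#' filtering, factorial differential expression, co-expression module
#' discovery with metrics, pre-defined module scoring and testing,
#' deconvolution, enrichment against all collections, phenotype analysis —
#' then enumeration of the bipartite graphs of the catalogue and union into
#' one association network. A failing dataset is recorded in the report and
#' does not abort the others.
#'
#' @param config a config list ([readRunConfig()]) or a path to a YAML file.
#' @return list with `graph` (the merged [AssociationGraph-class]),
#'   `report` (per-dataset and global build statistics) and `stages` (per
#'   dataset: the intermediate results of every analytic layer).
#' @export
buildAll <- function(config) {
  if (is.character(config)) config <- readRunConfig(config)
  th <- utils::modifyList(.defaultThresholds(), config$thresholds %||% list())
  t0 <- Sys.time()
  graphs <- list()
  stages <- list()
  report <- list(project = config$project %||% "unnamed", datasets = list())

  for (ds in config$datasets) {
    sq <- ds$square
    res <- tryCatch({
      warns <- character(0)
      out <- withCallingHandlers(
        .buildDataset(ds, config$annotations, th),
        warning = function(w) {
          warns <<- c(warns, conditionMessage(w))
          invokeRestart("muffleWarning")
        })
      out$warnings <- warns
      out
    }, error = function(e) structure(list(error = conditionMessage(e)),
                                     class = "buildFailure"))
    if (inherits(res, "buildFailure")) {
      report$datasets[[sq]] <- list(error = res$error)
      next
    }
    graphs <- c(graphs, res$graphs)
    stages[[sq]] <- res
    counts <- do.call(rbind, lapply(res$graphs, function(g)
      data.frame(nodes = nodeCount(g), edges = edgeCount(g))))
    counts$index <- vapply(res$graphs, function(g)
      if (edgeCount(g)) g@edges$graph_index[1] else NA_real_, 0)
    report$datasets[[sq]] <- list(
      probes_raw = res$nRaw, probes_analysis = res$nAnalysis,
      modules = res$moduleSizes, graphs = counts,
      warnings = res$warnings)
  }
  if (!length(graphs)) stop("all datasets failed; nothing to merge")
  graph <- graphUnion(graphs)
  report$global <- list(
    nodes = nodeCount(graph), edges = edgeCount(graph),
    edge_types = sort(unique(graph@edges$type)),
    graph_indices = sort(unique(graph@edges$graph_index)),
    elapsed_sec = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  list(graph = graph, report = report, stages = stages)
}

## one dataset: all analytic stages + its share of the bipartite graphs
.buildDataset <- function(ds, annPaths, th) {
  ed <- as.character(ds$edge %||% "1")
  paths <- c(list(expression = ds$expression, pheno = ds$pheno), annPaths)
  inputs <- readInputs(paths, classVar = ds$class_var,
                       stratVar = ds$strat_var,
                       idVars = unlist(ds$id_vars) %||% character(0))
  ann <- inputs$annotations
  se0 <- inputs$se
  if (!is.null(ds$class_ref))
    S4Vectors::metadata(se0)$classRef <- ds$class_ref
  if (!is.null(ds$strat_ref))
    S4Vectors::metadata(se0)$stratRef <- ds$strat_ref
  seN <- normalizeExpression(se0)
  seF <- filterProbes(seN, "variance", q = th$variance_q)
  if (identical(th$wgcna_filter, "factorial"))
    seW <- filterProbes(seF, "factorial")
  else seW <- seF

  p2s <- ann@probe2symbol
  de <- fitFactorial(seF, coef = ds$coef %||% NULL, probe2symbol = p2s)
  analysisProbes <- rownames(exprs(seF))
  universe <- unique(stats::na.omit(unname(p2s[analysisProbes])))

  ## co-expression modules
  xw <- exprs(seW)
  sp <- pickSoftPower(xw)
  tom <- tomMatrix(xw, sp$power)
  det <- detectModules(tom, xw, minSize = th$min_module_size,
                       mergeCor = th$merge_cor)
  assignment <- det$assignment
  mods <- setdiff(sort(unique(assignment)), "grey")
  if (!length(mods)) stop("no co-expression modules found")
  mes <- moduleEigengenes(xw, assignment)
  modSymbols <- lapply(mods, function(m)
    unique(stats::na.omit(unname(p2s[names(assignment)[assignment == m]]))))
  names(modSymbols) <- mods

  ## enrichment: wgcna and baylor against pathway + marker collections
  markerColls <- ann@markerCollections
  pathColls <- ann@pathwayCollections
  predef <- ann@predefinedModules
  enrWpath <- lapply(seq_along(pathColls), function(i)
    enrichCollection(modSymbols, pathColls[[i]], universe, qCut = th$q_cutoff,
                     pCut = th$p_cutoff,
                     minKeep = th$min_keep_pathway[min(i, length(th$min_keep_pathway))],
                     maxKeep = th$max_keep))
  enrWmark <- lapply(markerColls, function(coll)
    enrichCollection(modSymbols, coll, universe, qCut = th$q_cutoff,
                     pCut = th$p_cutoff, minKeep = th$min_keep,
                     maxKeep = th$max_keep))
  enrBpath <- enrBmark <- list()
  if (length(predef)) {
    enrWbay <- enrichCollection(modSymbols, predef, universe,
                                qCut = th$q_cutoff, pCut = th$p_cutoff,
                                minKeep = th$min_keep, maxKeep = th$max_keep)
    enrBpath <- lapply(seq_along(pathColls), function(i)
      enrichCollection(predef, pathColls[[i]], universe, qCut = th$q_cutoff,
                       pCut = th$p_cutoff,
                       minKeep = th$min_keep_pathway[min(i, length(th$min_keep_pathway))],
                       maxKeep = th$max_keep))
    enrBmark <- lapply(markerColls, function(coll)
      enrichCollection(predef, coll, universe, qCut = th$q_cutoff,
                       pCut = th$p_cutoff, minKeep = th$min_keep,
                       maxKeep = th$max_keep))
  } else enrWbay <- NULL

  ## module metrics (signature collection = first marker collection)
  sigEnr <- if (length(enrWmark)) enrWmark[[1]][enrWmark[[1]]$retained, ] else NULL
  metrics <- moduleMetrics(mes, seF, enrichment = sigEnr)

  ## repertoire scoring and module-level DE
  repScore <- if (length(predef)) scoreRepertoire(de, predef, p2s,
                                                  qCut = th$repertoire_q)
              else NULL
  repDE <- if (length(predef)) moduleDE(seF, predef, p2s,
                                        coef = ds$coef %||% NULL)
           else NULL

  ## deconvolution
  haveBasis <- nrow(ann@basis) > 0
  props <- if (haveBasis) estimateProportions(seN, ann@basis) else NULL
  propTest <- if (haveBasis) compareProportions(props$proportions, seN) else NULL

  ## phenotype
  phe <- encodePheno(phenoData(seN),
                     idVars = S4Vectors::metadata(seN)$idVars)
  uni <- phenoUnivariate(seN)
  corPheno <- correlateME(mes, phe$matrix, qCut = th$q_cutoff)
  corProp <- if (haveBasis)
    correlateME(mes, props$proportions, qCut = th$q_cutoff) else NULL

  sq <- ds$square
  graphs <- list()
  add <- function(g) graphs[[length(graphs) + 1]] <<- g

  ## -- mapping graphs -------------------------------------------------
  allProbes <- rownames(exprs(seN))
  mapped <- allProbes[!is.na(p2s[allProbes])]
  ## 1: platform-wide PROBETYPE -> SYMBOL
  add(.bulkGraph(edges = .edgesDF(nodeKey("PROBETYPE", mapped),
                                  nodeKey("SYMBOL", unname(p2s[mapped])),
                                  "mapping", 1)))
  ## 2: analysis PROBE -> SYMBOL, probes annotated with the DE result
  deMap <- de[!is.na(de$symbol), , drop = FALSE]
  add(.bulkGraph(
    nodes = .nodesDF("PROBE", deMap$probe, sq, ed,
                     props = .rowProps(deMap, c("logfc", "t", "p", "q"))),
    edges = .edgesDF(nodeKey("PROBE", deMap$probe, sq, ed),
                     nodeKey("SYMBOL", deMap$symbol), "mapping", 2)))
  ## 3: PROBE -> wgcna membership; wgcna nodes carry the module metrics
  inMod <- names(assignment)[assignment != "grey"]
  add(.bulkGraph(
    nodes = .nodesDF("wgcna", metrics$module, sq, ed,
                     props = .rowProps(metrics, c("modAUC1", "modAUC2",
                                                  "diffME", "sigenrich"))),
    edges = .edgesDF(nodeKey("PROBE", inMod, sq, ed),
                     nodeKey("wgcna", assignment[inMod], sq, ed),
                     "mapping", 3)))
  ## 4: thinned intra-module PROBE -- PROBE connectivity
  thin <- do.call(rbind, lapply(mods, function(m)
    selectModuleEdges(tom, names(assignment)[assignment == m],
                      frac = th$edge_frac, cap = th$edge_cap)))
  add(.bulkGraph(edges = .edgesDF(
    nodeKey("PROBE", thin$probe1, sq, ed),
    nodeKey("PROBE", thin$probe2, sq, ed),
    "correlation", 4,
    props = lapply(thin$weight, function(w) list(weight = w)))))
  ## 5-7: SYMBOL -> pathway mappings (symbols measured in this dataset)
  for (i in seq_along(pathColls)) {
    coll <- pathColls[[i]]
    long <- data.frame(
      set = rep(names(coll), lengths(coll)),
      symbol = unlist(coll, use.names = FALSE), stringsAsFactors = FALSE)
    long <- long[long$symbol %in% universe, , drop = FALSE]
    add(.bulkGraph(edges = .edgesDF(nodeKey("SYMBOL", long$symbol),
                                    nodeKey(PATHWAY_LABELS[i], long$set),
                                    "mapping", 4 + i)))
  }
  ## 8-10: SYMBOL -> cellEx marker mappings
  for (i in seq_along(markerColls)) {
    coll <- markerColls[[i]]
    long <- data.frame(
      set = rep(names(coll), lengths(coll)),
      symbol = unlist(coll, use.names = FALSE), stringsAsFactors = FALSE)
    long <- long[long$symbol %in% universe, , drop = FALSE]
    add(.bulkGraph(edges = .edgesDF(nodeKey("SYMBOL", long$symbol),
                                    nodeKey("cellEx", long$set),
                                    "mapping", 7 + i)))
  }

  ## -- enrichment graphs ----------------------------------------------
  if (!is.null(enrWbay)) {
    ## baylor nodes carry repertoire score and module-level test results
    bayProps <- rep(list(list()), length(predef))
    names(bayProps) <- names(predef)
    if (!is.null(repScore) && nrow(repScore)) {
      pr <- .rowProps(repScore, c("pct_up", "pct_down", "score"))
      bayProps[repScore$module] <- pr
    }
    if (!is.null(repDE) && nrow(repDE)) {
      for (i in seq_len(nrow(repDE))) {
        m <- repDE$probe[i]
        bayProps[[m]] <- utils::modifyList(
          bayProps[[m]] %||% list(),
          list(logfc = repDE$logfc[i], t = repDE$t[i],
               p = repDE$p[i], q = repDE$q[i]))
      }
    }
    add(.bulkGraph(nodes = .nodesDF("baylor", names(predef), sq, ed,
                                    props = unname(bayProps))))
    add(.enrichGraph(enrWbay, 11, "wgcna", sq, ed, "baylor"))
    for (i in seq_along(enrBpath))
      add(.enrichGraph(enrBpath[[i]], 11 + i, "baylor", sq, ed,
                       PATHWAY_LABELS[i]))
    for (i in seq_along(enrBmark))
      add(.enrichGraph(enrBmark[[i]], 17 + i, "baylor", sq, ed, "cellEx"))
  }
  for (i in seq_along(enrWpath))
    add(.enrichGraph(enrWpath[[i]], 14 + i, "wgcna", sq, ed,
                     PATHWAY_LABELS[i]))
  for (i in seq_along(enrWmark))
    add(.enrichGraph(enrWmark[[i]], 20 + i, "wgcna", sq, ed, "cellEx"))

  ## -- correlation + cell graphs ---------------------------------------
  if (haveBasis) {
    ## 24: ME -- cell proportion correlations; cellprop nodes carry the
    ## proportion difference tests
    add(.bulkGraph(
      nodes = .nodesDF("cellprop", propTest$cell, sq, ed,
                       props = .rowProps(propTest, c("diffP", "diffQ", "delta"))),
      edges = if (any(corProp$kept)) {
        kp <- corProp[corProp$kept, , drop = FALSE]
        .edgesDF(nodeKey("wgcna", kp$module, sq, ed),
                 nodeKey("cellprop", kp$target, sq, ed),
                 "correlation", 24,
                 props = .rowProps(kp, c("R", "p", "q")))
      } else NULL))
    ## 28: consensus CELL -> cellprop nodes of this dataset
    cellMap <- ann@cellNameMap
    propCells <- propTest$cell
    consensus <- ifelse(is.na(cellMap[propCells]), propCells,
                        unname(cellMap[propCells]))
    add(.bulkGraph(edges = .edgesDF(nodeKey("CELL", consensus),
                                    nodeKey("cellprop", propCells, sq, ed),
                                    "mapping", 28)))
  }
  ## 25-27: consensus CELL -> collection-specific cellEx labels
  for (i in seq_along(markerColls)) {
    labels <- names(markerColls[[i]])
    add(.bulkGraph(edges = .edgesDF(
      nodeKey("CELL", unname(ann@cellNameMap[labels])),
      nodeKey("cellEx", labels), "mapping", 24 + i)))
  }
  ## 29: ME -- phenotype correlations; pheno nodes carry univariate tests
  phenoProps <- .rowProps(uni, c("p", "q"))
  names(phenoProps) <- uni$variable
  encVars <- colnames(phe$matrix)
  add(.bulkGraph(
    nodes = .nodesDF("pheno", encVars, sq, ed,
                     props = lapply(encVars, function(v)
                       phenoProps[[v]] %||% list())),
    edges = if (any(corPheno$kept)) {
      kp <- corPheno[corPheno$kept, , drop = FALSE]
      .edgesDF(nodeKey("wgcna", kp$module, sq, ed),
               nodeKey("pheno", kp$target, sq, ed),
               "correlation", 29,
               props = .rowProps(kp, c("R", "p", "q")))
    } else NULL))

  ## virtual cells + activity (not part of the 29 graphs; returned as stages)
  links <- if (haveBasis && length(enrWmark)) {
    allMark <- do.call(rbind, enrWmark)
    linkModulesToCells(mes, props$proportions, allMark, ann@cellNameMap,
                       qCut = th$q_cutoff)
  } else NULL
  vcells <- list()
  if (!is.null(links) && nrow(links)) {
    allPath <- do.call(rbind, enrWpath)
    for (cell in unique(links$cell))
      vcells[[cell]] <- buildVirtualCell(links, assignment, seF, de,
                                         allPath, cell)
  }
  activity <- if (length(vcells)) {
    allSets <- do.call(c, unname(pathColls))
    cellPathwayActivity(vcells, allSets, de, p2s,
                        instance = function(cell)
                          paste(sq, ed, cell, sep = "_"))
  } else NULL

  list(se = seN, seF = seF, annotations = ann, de = de,
       softPower = sp$power, tom_dim = nrow(tom), assignment = assignment,
       mes = mes, metrics = metrics, repertoire = repScore,
       repertoireDE = repDE, proportions = props, proportionTests = propTest,
       phenoEncoding = phe, phenoUnivariate = uni, links = links,
       vcells = vcells, activity = activity,
       nRaw = nrow(exprs(seN)), nAnalysis = length(analysisProbes),
       moduleSizes = table(assignment[assignment != "grey"]),
       graphs = graphs)
}

#' Write a build report
#'
#' Emits the per-dataset and global statistics of a [buildAll()] run as a
#' JSON file and a human-readable `session_output.txt`-style text log.
#'
#' @param report the `report` element of a [buildAll()] result.
#' @param dir output directory.
#' @return invisibly, the paths written.
#' @export
writeBuildReport <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonPath <- file.path(dir, "build_report.json")
  rep2 <- report
  for (sq in names(rep2$datasets)) {
    d <- rep2$datasets[[sq]]
    if (!is.null(d$modules)) d$modules <- as.list(d$modules)
    rep2$datasets[[sq]] <- d
  }
  jsonlite::write_json(rep2, jsonPath, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  txtPath <- file.path(dir, "session_output.txt")
  con <- file(txtPath, "w")
  on.exit(close(con))
  cat("project:", report$project, "\n", file = con)
  for (sq in names(report$datasets)) {
    d <- report$datasets[[sq]]
    cat("\ndataset:", sq, "\n", file = con)
    if (!is.null(d$error)) {
      cat("  FAILED:", d$error, "\n", file = con)
      next
    }
    cat("  probes raw/analysis:", d$probes_raw, "/", d$probes_analysis,
        "\n", file = con)
    cat("  modules:", paste(sprintf("%s(%d)", names(d$modules),
                                    as.integer(d$modules)), collapse = " "),
        "\n", file = con)
    for (w in d$warnings) cat("  warning:", w, "\n", file = con)
  }
  g <- report$global
  cat("\nglobal:", g$nodes, "nodes,", g$edges, "edges;",
      length(g$graph_indices), "graph types;",
      "edge types:", paste(g$edge_types, collapse = ", "), ";",
      sprintf("%.1f s elapsed", g$elapsed_sec), "\n", file = con)
  invisible(c(jsonPath, txtPath))
}
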