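## Virtual cells: modules linked to cell types by the conjunction of
## eigengene-proportion correlation and marker enrichment; probe sets
## assembled per cell with co-expression, pathway and DE annotation; and
## cell x pathway activity matrices with up/down kept separate.

#' Link co-expression modules to cell types
#'
#' A (module, cell) link is created iff (a) the BH-q of the correlation
#' between the module eigengene and that cell's estimated proportion is
#' below `qCut` (family: all module x cell pairs in the dataset) AND (b)
#' the module has at least one retained marker-collection enrichment whose
#' cell label maps to that consensus cell. The link carries the correlation
#' R and the minimum enrichment q.
#'
#' @param mes modules x samples eigengene matrix.
#' @param proportions samples x cell types matrix; column names must map to
#'   consensus names via `cellNameMap` (or be consensus names already).
#' @param markerEnrichment combined [enrichCollection()] results over the
#'   marker collections (rows with `retained == TRUE` are considered);
#'   `set` holds the collection-specific cell label.
#' @param cellNameMap named map, cell label -> consensus cell name.
#' @param qCut correlation-edge cutoff; default 0.05.
#' @return data.frame: module, cell, R, corQ, enrichQ.
#' @export
linkModulesToCells <- function(mes, proportions, markerEnrichment,
                               cellNameMap, qCut = 0.05) {
  cellOf <- function(lbl) {
    out <- unname(cellNameMap[lbl])
    ifelse(is.na(out), lbl, out)
  }
  corEdges <- correlateME(mes, proportions, qCut = qCut)
  corEdges$cell <- cellOf(corEdges$target)
  enr <- markerEnrichment[markerEnrichment$retained, , drop = FALSE]
  rows <- list()
  if (nrow(enr)) enr$cell <- cellOf(enr$set)
  for (i in which(corEdges$kept)) {
    m <- corEdges$module[i]
    cell <- corEdges$cell[i]
    hits <- enr[enr$module == m & enr$cell == cell, , drop = FALSE]
    if (!nrow(hits)) next
    rows[[length(rows) + 1]] <- data.frame(
      module = m, cell = cell, R = corEdges$R[i], corQ = corEdges$q[i],
      enrichQ = min(hits$q), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(module = character(0), cell = character(0),
                      R = numeric(0), corQ = numeric(0), enrichQ = numeric(0))
  out
}

#' Assemble a virtual cell
#'
#' The probe set is the union of the probes of all modules linked to the
#' cell; the co-expression matrix is the Pearson correlation of those
#' probes on the normalized data; pathway annotation and per-probe
#' differential expression are carried along.
#'
#' @param links [linkModulesToCells()] output.
#' @param assignment named probe -> module vector.
#' @param se normalized experiment.
#' @param de [fitFactorial()] result for the dataset contrast.
#' @param pathwayEnrichment combined pathway [enrichCollection()] results.
#' @param cell consensus cell name.
#' @return list of class `VirtualCell`: `cell`, `modules`, `probes`,
#'   `coexpression` (symmetric, unit diagonal), `pathways`, `de`.
#' @export
buildVirtualCell <- function(links, assignment, se, de, pathwayEnrichment,
                             cell) {
  mods <- links$module[links$cell == cell]
  if (!length(mods))
    stop("no modules linked to cell '", cell, "'; available: ",
         paste(unique(links$cell), collapse = ", "))
  probes <- sort(unique(names(assignment)[assignment %in% mods]))
  cc <- cor(t(exprs(se)[probes, , drop = FALSE]))
  pw <- pathwayEnrichment[pathwayEnrichment$retained &
                            pathwayEnrichment$module %in% mods, , drop = FALSE]
  structure(list(cell = cell, modules = sort(unique(mods)), probes = probes,
                 coexpression = cc, pathways = pw,
                 de = de[de$probe %in% probes, , drop = FALSE]),
            class = "VirtualCell")
}

#' Cell x pathway activity
#'
#' For each virtual cell and pathway, the contributing probes are the
#' cell's probes that map to the pathway's symbols. The up (down) activity
#' is the mean of the positive (negative) log2 fold changes among those
#' probes; directions are kept separate and combinations with no
#' contributing probes are absent (not zero).
#'
#' @param vcells list of `VirtualCell` objects.
#' @param pathways named list of symbol sets.
#' @param de [fitFactorial()] result (probe-level logfc).
#' @param probe2symbol named probe -> symbol map.
#' @param qCut optional significance filter on contributing probes
#'   (default NULL: all probes of the intersection contribute).
#' @param instance function(cell) -> column label; defaults to the cell
#'   name itself.
#' @return data.frame (long form): cell_instance, cell, pathway, direction
#'   ("up"/"down"), score, n_probes.
#' @export
cellPathwayActivity <- function(vcells, pathways, de, probe2symbol,
                                qCut = NULL, instance = identity) {
  logfc <- setNames(de$logfc, de$probe)
  qv <- setNames(de$q, de$probe)
  rows <- list()
  for (vc in vcells) {
    lbl <- instance(vc$cell)
    for (pw in names(pathways)) {
      pwProbes <- names(probe2symbol)[probe2symbol %in% pathways[[pw]]]
      shared <- intersect(vc$probes, pwProbes)
      shared <- shared[shared %in% names(logfc)]
      if (!is.null(qCut)) shared <- shared[qv[shared] < qCut]
      if (!length(shared)) next
      lf <- logfc[shared]
      if (any(lf > 0))
        rows[[length(rows) + 1]] <- data.frame(
          cell_instance = lbl, cell = vc$cell, pathway = pw,
          direction = "up", score = mean(lf[lf > 0]),
          n_probes = sum(lf > 0), stringsAsFactors = FALSE)
      if (any(lf < 0))
        rows[[length(rows) + 1]] <- data.frame(
          cell_instance = lbl, cell = vc$cell, pathway = pw,
          direction = "down", score = mean(lf[lf < 0]),
          n_probes = sum(lf < 0), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(cell_instance = character(0), cell = character(0),
                      pathway = character(0), direction = character(0),
                      score = numeric(0), n_probes = integer(0))
  out
}

#' Rank pathways and cells by total activity
#'
#' Pathway scores are row sums (over cell instances) and cell scores are
#' column sums (over pathways) of the activity matrix, with up and down
#' directions summed separately; descending order, ties broken by name.
#'
#' @param activity long-form activity data.frame ([cellPathwayActivity()]).
#' @return list with `pathways` and `cells` data.frames (name, direction,
#'   total), each sorted by decreasing |total| within direction.
#' @export
rankActivity <- function(activity) {
  if (!nrow(activity)) stop("empty activity matrix")
  agg <- function(key) {
    s <- aggregate(score ~ get(key) + direction, data = activity, FUN = sum)
    names(s)[1] <- "name"
    s <- s[order(s$direction, -abs(s$score), s$name), ]
    rownames(s) <- NULL
    names(s)[3] <- "total"
    s
  }
  list(pathways = agg("pathway"), cells = agg("cell_instance"))
}

#' Compare cell activity across datasets
#'
#' Selects the cell-type instances matching `cellFilter` (a regular
#' expression on the instance label) in each dataset's activity table,
#' assembles the (pathway x direction) by instance matrix over the union of
#' pathways, and orders columns by average-linkage hierarchical clustering
#' of Euclidean distances. Missing (pathway, instance) entries are treated
#' as 0 inside the clustering distance only and reported as NA.
#'
#' @param activities named list of [cellPathwayActivity()] outputs, one per
#'   dataset.
#' @param cellFilter regular expression selecting instance labels.
#' @return list with `matrix` (rows "pathway|direction", columns instances,
#'   NA = absent), `order` (clustered column order) and `hclust`.
#' @export
metaCellCompare <- function(activities, cellFilter = ".") {
  if (length(activities) < 2) stop("need >= 2 datasets")
  long <- do.call(rbind, lapply(names(activities), function(ds) {
    a <- activities[[ds]]
    a$instance <- paste(ds, a$cell_instance, sep = "_")
    a
  }))
  long <- long[grepl(cellFilter, long$instance), , drop = FALSE]
  if (!nrow(long)) stop("cell filter matches no instances")
  rowsKey <- sort(unique(paste(long$pathway, long$direction, sep = "|")))
  colsKey <- sort(unique(long$instance))
  mat <- matrix(NA_real_, length(rowsKey), length(colsKey),
                dimnames = list(rowsKey, colsKey))
  mat[cbind(paste(long$pathway, long$direction, sep = "|"), long$instance)] <-
    long$score
  filled <- mat
  filled[is.na(filled)] <- 0
  hc <- if (ncol(mat) > 2) hclust(dist(t(filled)), method = "average") else NULL
  ord <- if (is.null(hc)) seq_len(ncol(mat)) else hc$order
  list(matrix = mat[, ord, drop = FALSE], order = colnames(mat)[ord],
       hclust = hc)
}
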