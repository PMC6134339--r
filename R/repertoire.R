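## Pre-defined (repertoire-style) transcriptional modules: per-contrast
## percent-up/percent-down scores, module-level moderated tests, and the
## cross-dataset meta-analysis matrix.

#' Score pre-defined modules against a differential-expression result
#'
#' For each module, member probes are the probes mapping to the module's
#' symbols. `pct_up` / `pct_down` are the percentages of member probes
#' significantly up- / down-regulated (q < `qCut`, logfc > 0 / < 0) and the
#' module score is `pct_up - pct_down`, in `[-100, 100]`. Modules with no
#' mapped probes are excluded and listed in the `"unmapped"` attribute.
#'
#' @param de [fitFactorial()] result.
#' @param defs named list of symbol sets (fixed module definitions).
#' @param probe2symbol named probe -> symbol map.
#' @param qCut significance cutoff; default 0.05.
#' @return data.frame: module, n_probes, pct_up, pct_down, score.
#' @export
scoreRepertoire <- function(de, defs, probe2symbol, qCut = 0.05) {
  if (!length(defs)) stop("empty module definition set")
  symbols <- unname(probe2symbol[de$probe])
  rows <- lapply(names(defs), function(m) {
    hit <- !is.na(symbols) & symbols %in% defs[[m]]
    if (!any(hit)) return(NULL)
    up <- 100 * mean(de$q[hit] < qCut & de$logfc[hit] > 0, na.rm = TRUE)
    dn <- 100 * mean(de$q[hit] < qCut & de$logfc[hit] < 0, na.rm = TRUE)
    data.frame(module = m, n_probes = sum(hit), pct_up = up, pct_down = dn,
               score = up - dn, stringsAsFactors = FALSE)
  })
  unmapped <- names(defs)[vapply(rows, is.null, TRUE)]
  out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(out))
    out <- data.frame(module = character(0), n_probes = integer(0),
                      pct_up = numeric(0), pct_down = numeric(0),
                      score = numeric(0))
  attr(out, "unmapped") <- unmapped
  attr(out, "definitions") <- names(defs)
  out
}

#' Module-level differential expression
#'
#' Summarizes each pre-defined module as the unweighted mean log2 expression
#' of its mapped probes per sample, applies the factorial moderated-t model
#' to the module x sample summary matrix and BH-adjusts across modules.
#'
#' @param se normalized `SummarizedExperiment`.
#' @param defs named list of symbol sets.
#' @param probe2symbol named probe -> symbol map.
#' @param coef contrast, as in [fitFactorial()].
#' @return data.frame as [fitFactorial()], one row per mapped module
#'   (`probe` column holds the module name).
#' @export
moduleDE <- function(se, defs, probe2symbol, coef = NULL) {
  if (!length(defs)) stop("empty module definition set")
  x <- exprs(se)
  symbols <- unname(probe2symbol[rownames(x)])
  summary <- lapply(names(defs), function(m) {
    hit <- !is.na(symbols) & symbols %in% defs[[m]]
    if (!any(hit)) return(NULL)
    colMeans(x[hit, , drop = FALSE])
  })
  keep <- !vapply(summary, is.null, TRUE)
  if (sum(keep) < 2) stop("fewer than 2 modules map to the data")
  smat <- do.call(rbind, summary[keep])
  rownames(smat) <- names(defs)[keep]
  se2 <- se[seq_len(1), ]      # carry design metadata; replace assay wholesale
  se2 <- SummarizedExperiment::SummarizedExperiment(
    assays = list(exprs = smat),
    colData = SummarizedExperiment::colData(se))
  S4Vectors::metadata(se2) <- S4Vectors::metadata(se)
  fitFactorial(se2, coef = coef)
}

#' Cross-dataset repertoire meta-analysis
#'
#' Assembles the modules x datasets score matrix and the subset of modules
#' expressed in the same (strictly nonzero) direction in every dataset.
#' All datasets must have been scored against the same definition set.
#'
#' @param results named list of [scoreRepertoire()] outputs, one per dataset.
#' @return list with `matrix` (modules x datasets; NA where a module was
#'   unmapped), `consistent` (character vector of same-direction modules)
#'   and `order` (row order from average-linkage clustering, for plotting).
#' @export
metaRepertoire <- function(results) {
  if (length(results) < 2) stop("need >= 2 datasets for meta-analysis")
  defs <- lapply(results, attr, "definitions")
  if (!all(vapply(defs, identical, TRUE, defs[[1]])))
    stop("datasets were scored against different module definition sets")
  mods <- lapply(results, function(r) r$module)
  common <- Reduce(union, mods)
  mat <- vapply(results, function(r) {
    v <- setNames(rep(NA_real_, length(common)), common)
    v[r$module] <- r$score
    v
  }, numeric(length(common)))
  if (is.null(dim(mat))) mat <- matrix(mat, ncol = length(results),
                                       dimnames = list(common, names(results)))
  sgn <- sign(mat)
  consistent <- rownames(mat)[apply(sgn, 1, function(s)
    all(!is.na(s)) && all(s != 0) && length(unique(s)) == 1)]
  ord <- if (nrow(mat) > 2) {
    filled <- mat
    filled[is.na(filled)] <- 0
    hclust(dist(filled), method = "average")$order
  } else seq_len(nrow(mat))
  list(matrix = mat, consistent = consistent, order = ord)
}
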