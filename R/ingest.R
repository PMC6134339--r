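## Input ingestion: alignment of expression and phenotype by shared sample
## ids, log2 + quantile normalization, and probe filtering.

#' Assemble an expression experiment
#'
#' Wraps a probes x samples matrix and a phenotype table into a
#' `SummarizedExperiment` (assay `"exprs"`). The phenotype's class and
#' stratification variables and the normalization state are recorded in the
#' object metadata.
#'
#' @param expr numeric matrix, probes x samples.
#' @param pheno data.frame of per-sample variables, rownames = sample ids.
#' @param classVar,stratVar names of the two categorical design variables.
#' @param classRef,stratRef reference (baseline) levels for the design; by
#'   default the alphabetically first level. Contrasts and module metrics
#'   are oriented towards the non-reference level.
#' @param idVars character vector of identifier variables (never analysed).
#' @param normalized logical flag; FALSE for raw intensities.
#' @return a `SummarizedExperiment`.
#' @export
makeExperiment <- function(expr, pheno, classVar, stratVar,
                           classRef = NULL, stratRef = NULL,
                           idVars = character(0), normalized = FALSE) {
  stopifnot(!anyDuplicated(rownames(expr)), !anyDuplicated(colnames(expr)))
  if (!identical(colnames(expr), rownames(pheno)))
    stop("expression columns and phenotype rows must agree")
  for (v in c(classVar, stratVar)) {
    if (!v %in% names(pheno)) stop("phenotype variable not found: ", v)
    if (length(unique(pheno[[v]])) < 2)
      stop("design variable ", v, " must have >= 2 levels")
  }
  if (is.null(classRef)) classRef <- sort(unique(as.character(pheno[[classVar]])))[1]
  if (is.null(stratRef)) stratRef <- sort(unique(as.character(pheno[[stratVar]])))[1]
  if (!classRef %in% pheno[[classVar]] || !stratRef %in% pheno[[stratVar]])
    stop("reference level not present in the phenotype")
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(exprs = expr),
    colData = S4Vectors::DataFrame(pheno, check.names = FALSE))
  S4Vectors::metadata(se) <- list(normalized = normalized, classVar = classVar,
                                  stratVar = stratVar, classRef = classRef,
                                  stratRef = stratRef, idVars = idVars)
  se
}

#' @rdname makeExperiment
#' @param se a `SummarizedExperiment` built by [makeExperiment()].
#' @export
exprs <- function(se) SummarizedExperiment::assay(se, "exprs")

#' @rdname makeExperiment
#' @export
phenoData <- function(se) as.data.frame(SummarizedExperiment::colData(se))

#' @rdname makeExperiment
#' @export
isNormalized <- function(se) isTRUE(S4Vectors::metadata(se)$normalized)

#' Read and align all build inputs
#'
#' Reads the expression TSV and phenotype CSV, aligns them on the
#' intersection of sample ids (expression-file order kept), and reads the
#' annotation fixtures into an [AnnotationBundle-class]. Dropped samples are
#' reported with a warning; an empty intersection is fatal.
#'
#' @param paths named list: `expression`, `pheno`, and optionally
#'   `probe2symbol`, `markers` (named list of GMTs), `pathways` (named list
#'   of GMTs), `predefined_modules`, `basis`, `cellmap`.
#' @param classVar,stratVar names of the design variables in the phenotype.
#' @param idVars identifier variables in the phenotype.
#' @return list with `se` (un-normalized `SummarizedExperiment`) and
#'   `annotations` ([AnnotationBundle-class]).
#' @export
readInputs <- function(paths, classVar, stratVar, idVars = character(0)) {
  expr <- readExpression(paths$expression)
  pheno <- readPheno(paths$pheno)
  shared <- intersect(colnames(expr), rownames(pheno))
  if (!length(shared))
    stop("no shared sample ids between expression and phenotype inputs")
  dropExpr <- setdiff(colnames(expr), shared)
  dropPheno <- setdiff(rownames(pheno), shared)
  if (length(dropExpr) || length(dropPheno))
    warning(sprintf("dropped %d expression / %d phenotype samples without a match",
                    length(dropExpr), length(dropPheno)))
  keep <- colnames(expr)[colnames(expr) %in% shared]   # expression order
  expr <- expr[, keep, drop = FALSE]
  pheno <- pheno[keep, , drop = FALSE]

  p2s <- if (!is.null(paths$probe2symbol)) readProbe2Symbol(paths$probe2symbol)
         else character(0)
  readColl <- function(x) {
    if (is.null(x)) return(list())
    out <- lapply(x, readGMT)
    lapply(out, function(s) { attributes(s) <- list(names = names(s)); s })
  }
  markers <- readColl(paths$markers)
  pathways <- readColl(paths$pathways)
  predef <- if (!is.null(paths$predefined_modules)) {
    s <- readGMT(paths$predefined_modules)
    attributes(s) <- list(names = names(s)); s
  } else list()
  basis <- if (!is.null(paths$basis)) readBasis(paths$basis)
           else matrix(0, 0, 0)
  cellMap <- if (!is.null(paths$cellmap)) readCellMap(paths$cellmap)
             else character(0)
  ann <- new("AnnotationBundle", probe2symbol = p2s,
             pathwayCollections = pathways, markerCollections = markers,
             predefinedModules = predef, basis = basis,
             cellNameMap = cellMap)
  se <- makeExperiment(expr, pheno, classVar, stratVar, idVars = idVars)
  list(se = se, annotations = ann)
}

#' Normalize an expression experiment
#'
#' log2(x + 1) transform followed by quantile normalization across samples,
#' after which the sorted values of every column are identical; tied ranks
#' receive the mean of the target quantiles. Matrices containing values <= 0
#' (background-subtracted intensities) are first shifted by `1 - min`.
#'
#' @param se un-normalized `SummarizedExperiment` from [makeExperiment()].
#' @return the experiment with normalized log2 values and the `normalized`
#'   flag set.
#' @export
normalizeExpression <- function(se) {
  if (isNormalized(se)) stop("experiment is already normalized")
  x <- exprs(se)
  if (!all(is.finite(x))) stop("expression values must be finite")
  if (min(x) <= 0) x <- x + (1 - min(x))
  x <- log2(x + 1)
  if (ncol(x) >= 2) {
    x <- limma::normalizeQuantiles(x, ties = TRUE)
  } else {
    warning("single-sample matrix: quantile step skipped")
  }
  SummarizedExperiment::assay(se, "exprs") <- x
  S4Vectors::metadata(se)$normalized <- TRUE
  se
}

#' Filter probes
#'
#' `mode = "variance"` keeps probes whose variance is at or above the q-th
#' quantile of probe variances. `mode = "factorial"` fits the two-factor
#' design (class * strat) per probe and keeps probes with overall-F nominal
#' p < `pCut`, capped at the top `nMax` by F statistic. Retained probes keep
#' their original order.
#'
#' @param se normalized `SummarizedExperiment`.
#' @param mode `"variance"` or `"factorial"`.
#' @param q variance-quantile cutoff (default 0.5).
#' @param pCut nominal overall-F p cutoff (default 0.05).
#' @param nMax cap on retained probes in factorial mode (default 5000).
#' @return the filtered experiment.
#' @export
filterProbes <- function(se, mode = c("variance", "factorial"), q = 0.5,
                         pCut = 0.05, nMax = 5000) {
  mode <- match.arg(mode)
  if (!isNormalized(se)) stop("filterProbes expects normalized data")
  x <- exprs(se)
  if (mode == "variance") {
    v <- apply(x, 1, var)
    keep <- v >= quantile(v, q)
  } else {
    md <- S4Vectors::metadata(se)
    ph <- phenoData(se)
    f1 <- factor(ph[[md$classVar]])
    f2 <- factor(ph[[md$stratVar]])
    X <- model.matrix(~ f1 * f2)
    qrX <- qr(X)
    p <- qrX$rank
    n <- ncol(x)
    fit <- t(qr.resid(qrX, t(x)))
    rss1 <- rowSums(fit^2)
    rss0 <- rowSums((x - rowMeans(x))^2)
    Fstat <- ((rss0 - rss1) / (p - 1)) / (rss1 / (n - p))
    pF <- stats::pf(Fstat, p - 1, n - p, lower.tail = FALSE)
    keep <- pF < pCut
    if (sum(keep) > nMax) {
      thr <- sort(Fstat[keep], decreasing = TRUE)[nMax]
      keep <- keep & Fstat >= thr
    }
  }
  if (sum(keep) < 10)
    stop("probe filter retains fewer than 10 probes")
  se[keep, ]
}
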