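## Cell-type deconvolution: per-sample non-negative least squares on a
## linear-scale signature basis, sum-to-one renormalization, and
## non-parametric tests of proportion differences between classes.

#' Estimate cell-type proportions
#'
#' Each sample's linear-scale expression over the basis probes is regressed
#' on the signature basis by non-negative least squares; the coefficient
#' vector is renormalized to sum to 1. Normalized (log2) experiments are
#' restored to the linear scale (`2^x - 1`) before the fit. Samples whose
#' NNLS solution is identically zero receive uniform proportions with a
#' warning.
#'
#' @param se a `SummarizedExperiment` (normalized or raw).
#' @param basis numeric matrix, marker probes x cell types, linear scale.
#' @return data.frame-free list: `proportions` (samples x cell types, rows
#'   on the simplex) and `sharedProbes` (basis probes found in the data).
#' @export
estimateProportions <- function(se, basis) {
  if (ncol(basis) < 2) stop("basis needs >= 2 cell types")
  x <- exprs(se)
  shared <- intersect(rownames(basis), rownames(x))
  if (length(shared) < 0.5 * nrow(basis))
    warning("fewer than 50% of basis probes present in the expression data")
  if (length(shared) < 2 * ncol(basis))
    stop("too few shared probes (", length(shared),
         ") for ", ncol(basis), " cell types")
  y <- x[shared, , drop = FALSE]
  if (isNormalized(se)) y <- 2^y - 1
  B <- basis[shared, , drop = FALSE]
  props <- t(apply(y, 2, function(v) {
    sol <- pracma::lsqnonneg(B, v)$x
    if (all(sol == 0)) {
      warning("all-zero NNLS solution; uniform proportions assigned")
      sol <- rep(1, ncol(B))
    }
    sol / sum(sol)
  }))
  dimnames(props) <- list(colnames(x), colnames(basis))
  list(proportions = props, sharedProbes = shared)
}

#' Test group differences in cell-type proportions
#'
#' Two-sided Wilcoxon rank-sum test per cell type for a binary class
#' (Kruskal-Wallis for > 2 levels), BH-corrected across cell types.
#'
#' @param proportions samples x cell types matrix ([estimateProportions()]).
#' @param se the experiment providing the class variable.
#' @param classVar phenotype variable to test against; defaults to the
#'   experiment's class variable.
#' @return data.frame: cell, diffP (uncorrected), diffQ (BH across cells),
#'   delta (difference of medians, case minus control, binary case only).
#' @export
compareProportions <- function(proportions, se, classVar = NULL) {
  md <- S4Vectors::metadata(se)
  if (is.null(classVar)) classVar <- md$classVar
  cls <- factor(phenoData(se)[[classVar]])
  if (any(table(cls) < 2)) stop("each class level needs >= 2 samples")
  binary <- nlevels(cls) == 2
  ref <- if (identical(classVar, md$classVar)) md$classRef else levels(cls)[1]
  pos <- if (binary) as.character(cls) != ref else NULL
  res <- lapply(colnames(proportions), function(cell) {
    v <- proportions[, cell]
    if (binary) {
      p <- suppressWarnings(wilcox.test(v[pos], v[!pos], exact = FALSE)$p.value)
      d <- median(v[pos]) - median(v[!pos])
    } else {
      p <- kruskal.test(v, cls)$p.value
      d <- NA_real_
    }
    data.frame(cell = cell, diffP = p, delta = d, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$diffQ <- bhAdjust(out$diffP)
  out[, c("cell", "diffP", "diffQ", "delta")]
}
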