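## Phenotype encoding, univariate phenotype analysis, and eigengene
## correlation edges against encoded phenotypes or cell proportions.

#' Encode phenotype variables numerically
#'
#' Numeric variables pass through; categorical/ordinal variables are coded
#' as integers 0..k-1 in alphabetical level order (the order is recorded);
#' identifier variables are excluded; constant variables are dropped with a
#' warning.
#'
#' @param pheno data.frame of phenotype variables.
#' @param idVars character vector of identifier variable names.
#' @return list with `matrix` (samples x encoded variables), `levels`
#'   (recorded level order per encoded categorical) and `excluded`.
#' @export
encodePheno <- function(pheno, idVars = character(0)) {
  enc <- list()
  levs <- list()
  excluded <- idVars
  for (v in setdiff(names(pheno), idVars)) {
    x <- pheno[[v]]
    if (length(unique(x[!is.na(x)])) < 2) {
      warning("constant variable dropped: ", v)
      excluded <- c(excluded, v)
      next
    }
    if (is.numeric(x)) {
      enc[[v]] <- as.numeric(x)
    } else {
      lv <- sort(unique(as.character(x)))
      enc[[v]] <- as.numeric(match(as.character(x), lv) - 1L)
      levs[[v]] <- lv
    }
  }
  m <- do.call(cbind, enc)
  if (!is.null(m)) rownames(m) <- rownames(pheno)
  list(matrix = m, levels = levs, excluded = excluded)
}

#' Correlate module eigengenes with numeric targets
#'
#' Pearson (or Spearman) correlation of every module eigengene with every
#' target column (encoded phenotype variables or cell proportions), with
#' two-sided p-values and BH correction over all (module, target) pairs in
#' the family. Edges with q < `qCut` are flagged `kept`.
#'
#' @param mes modules x samples eigengene matrix.
#' @param targets samples x variables numeric matrix.
#' @param method "pearson" or "spearman".
#' @param qCut edge-retention cutoff; default 0.05.
#' @return data.frame: module, target, R, p, q, kept.
#' @export
correlateME <- function(mes, targets, method = c("pearson", "spearman"),
                        qCut = 0.05) {
  method <- match.arg(method)
  stopifnot(ncol(mes) == nrow(targets))
  if (ncol(mes) < 4) stop("need >= 4 paired observations")
  rows <- list()
  for (m in rownames(mes)) for (v in colnames(targets)) {
    y <- targets[, v]
    ok <- !is.na(y)
    if (sd(y[ok]) == 0) {
      message("zero-variance target skipped: ", v)
      next
    }
    ct <- suppressWarnings(cor.test(mes[m, ok], y[ok], method = method))
    rows[[length(rows) + 1]] <- data.frame(
      module = m, target = v, R = unname(ct$estimate), p = ct$p.value,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(module = character(0), target = character(0),
                      R = numeric(0), p = numeric(0), q = numeric(0),
                      kept = logical(0)))
  out$q <- bhAdjust(out$p)
  out$kept <- out$q < qCut
  rownames(out) <- NULL
  out
}

#' Univariate phenotype analysis against the class variable
#'
#' Numeric/ordinal variables: two-sided Wilcoxon rank-sum between the two
#' class levels. Categorical variables: Fisher's exact test on the
#' contingency table. BH correction across variables. Degenerate tables
#' yield p = 1 with a warning.
#'
#' @param se the experiment (class variable from metadata).
#' @param idVars identifier variables to skip (defaults to metadata).
#' @return data.frame: variable, test, p, q.
#' @export
phenoUnivariate <- function(se, idVars = NULL) {
  md <- S4Vectors::metadata(se)
  ph <- phenoData(se)
  if (is.null(idVars)) idVars <- md$idVars %||% character(0)
  cls <- factor(ph[[md$classVar]])
  if (nlevels(cls) != 2) stop("class variable must be binary")
  vars <- setdiff(names(ph), c(md$classVar, idVars))
  rows <- lapply(vars, function(v) {
    x <- ph[[v]]
    if (length(unique(x[!is.na(x)])) < 2) {
      warning("degenerate variable, p set to 1: ", v)
      return(data.frame(variable = v, test = "none", p = 1))
    }
    if (is.numeric(x)) {
      p <- suppressWarnings(
        wilcox.test(x ~ cls, exact = FALSE)$p.value)
      data.frame(variable = v, test = "wilcoxon", p = p)
    } else {
      tab <- table(x, cls)
      p <- tryCatch(fisher.test(tab)$p.value,
                    error = function(e) {
                      warning("degenerate table, p set to 1: ", v)
                      1
                    })
      data.frame(variable = v, test = "fisher", p = p)
    }
  })
  out <- do.call(rbind, rows)
  out$q <- bhAdjust(out$p)
  rownames(out) <- NULL
  out
}
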