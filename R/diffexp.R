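## Factorial differential expression with empirical-Bayes moderated t-tests
## (limma) and Benjamini-Hochberg adjustment.

#' Fit the factorial linear model with moderated t-tests
#'
#' Per-probe least squares on the design
#' `~ class * strat` (treatment coding, alphabetical reference level),
#' followed by empirical-Bayes variance moderation: the residual variances
#' are shrunk towards a prior (d0, s0^2) estimated from all probes, the
#' moderated t uses the posterior variance s2_post on d0 + d_g degrees of
#' freedom, and p-values are BH-adjusted. The reported contrast defaults to
#' the class main effect within the reference stratum.
#'
#' @param se normalized `SummarizedExperiment`.
#' @param coef coefficient reported as the contrast of interest; default the
#'   class main effect. One of `colnames(designMatrix(se))`.
#' @param moderated if FALSE, ordinary (un-moderated) OLS t statistics are
#'   returned — the d0 = 0 limit.
#' @param probe2symbol optional named map to attach symbols.
#' @return data.frame with one row per probe: `probe`, `symbol`, `logfc`,
#'   `t`, `p`, `q`, `s2`, `df_resid`, `df_prior`, `s2_prior`, `s2_post`.
#' @export
fitFactorial <- function(se, coef = NULL, moderated = TRUE,
                         probe2symbol = NULL) {
  X <- designMatrix(se)
  x <- exprs(se)
  ## complete-case per design: probes with missing values are dropped
  ok <- complete.cases(x)
  if (!all(ok)) {
    warning(sum(!ok), " probes with missing values dropped from the fit")
    x <- x[ok, , drop = FALSE]
  }
  if (qr(X)$rank < ncol(X)) {
    aliased <- colnames(X)[qr(X)$pivot[-seq_len(qr(X)$rank)]]
    stop("rank-deficient design; aliased column(s): ",
         paste(aliased, collapse = ", "))
  }
  if (nrow(x) < 2) stop("need at least two probes")
  fit <- limma::lmFit(x, X)
  if (is.null(coef)) coef <- colnames(X)[2]   # class main effect
  if (!coef %in% colnames(X))
    stop("unknown coefficient: ", coef, " (available: ",
         paste(colnames(X), collapse = ", "), ")")
  if (moderated) {
    eb <- limma::eBayes(fit)
    tstat <- eb$t[, coef]
    p <- eb$p.value[, coef]
    dfPrior <- eb$df.prior
    s2Prior <- eb$s2.prior
    s2Post <- eb$s2.post
  } else {
    sigma <- fit$sigma
    tstat <- fit$coefficients[, coef] / (fit$stdev.unscaled[, coef] * sigma)
    p <- 2 * pt(-abs(tstat), fit$df.residual)
    dfPrior <- 0
    s2Prior <- NA_real_
    s2Post <- sigma^2
  }
  p[fit$df.residual == 0] <- 1              # no residual df: uninformative
  if (any(fit$df.residual == 0))
    warning("probes with zero residual df assigned p = 1")
  res <- data.frame(
    probe = rownames(x),
    symbol = if (!is.null(probe2symbol)) unname(probe2symbol[rownames(x)])
             else NA_character_,
    logfc = fit$coefficients[, coef],
    t = tstat, p = p, q = bhAdjust(p),
    s2 = fit$sigma^2, df_resid = fit$df.residual,
    df_prior = rep(dfPrior, length.out = nrow(x)),
    s2_prior = rep(s2Prior, length.out = nrow(x)),
    s2_post = s2Post,
    row.names = NULL, stringsAsFactors = FALSE)
  attr(res, "coef") <- coef
  attr(res, "design") <- colnames(X)
  res
}

#' Design matrix of the two-factor experiment
#'
#' Treatment coding with alphabetical reference levels:
#' `~ class * strat` giving intercept, class main effect, stratum main
#' effect and interaction.
#'
#' @param se a `SummarizedExperiment` from [makeExperiment()].
#' @return the model matrix.
#' @export
designMatrix <- function(se) {
  md <- S4Vectors::metadata(se)
  ph <- phenoData(se)
  f1 <- stats::relevel(factor(ph[[md$classVar]]), ref = md$classRef)
  f2 <- stats::relevel(factor(ph[[md$stratVar]]), ref = md$stratRef)
  X <- model.matrix(~ f1 * f2)
  colnames(X) <- sub("^f1", paste0(md$classVar, "_"), colnames(X))
  colnames(X) <- sub("f2", paste0(md$stratVar, "_"), colnames(X))
  X
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment: `q_i = min_{j >= rank(i)} m * p_(j) / j`, clipped
#' at 1. NA/NaN entries propagate and are excluded from the family size m.
#' The result is invariant to the order of the input.
#'
#' @param p numeric vector of p-values in `[0, 1]` (NAs allowed).
#' @return vector of adjusted q-values.
#' @export
bhAdjust <- function(p) {
  q <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p-values must lie in [0, 1]")
  q[ok] <- p.adjust(p[ok], method = "BH")
  q
}
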