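## Weighted co-expression analysis: soft-threshold selection, topological
## overlap, module detection by average-linkage clustering of 1 - TOM with a
## static cut and eigengene-based merging, module eigengenes and metrics,
## and intra-module edge thinning.

## Canonical module colour sequence (largest module first; "grey" is
## reserved for unassigned probes).
MODULE_COLOURS <- c(
  "turquoise", "blue", "brown", "yellow", "green", "red", "black", "pink",
  "magenta", "purple", "greenyellow", "tan", "salmon", "cyan",
  "midnightblue", "lightcyan", "grey60", "lightgreen", "lightyellow",
  "royalblue", "darkred", "darkgreen", "darkturquoise", "darkgrey",
  "orange", "darkorange", "white", "skyblue", "saddlebrown", "steelblue",
  "paleturquoise", "violet", "darkolivegreen", "darkmagenta")

#' Choose the soft-thresholding power
#'
#' Evaluates unsigned adjacencies `|cor|^beta` for beta in `powers` and
#' returns the smallest beta whose scale-free topology fit reaches
#' `rsqCut`. The fit is the signed R-squared of the regression of
#' `log10 p(k)` on `log10 k` over 10 connectivity bins (sign flipped so a
#' decreasing degree distribution scores positively). If no power
#' qualifies, the conventional default of 6 is returned with a warning.
#'
#' @param expr numeric matrix, probes x samples (log2, filtered).
#' @param powers candidate integer powers; default 1:20.
#' @param rsqCut fit threshold; default 0.8.
#' @param nBins connectivity bins; default 10.
#' @return list with `power`, and `fitTable` (beta, fit R^2, mean k).
#' @export
pickSoftPower <- function(expr, powers = 1:20, rsqCut = 0.8, nBins = 10) {
  if (nrow(expr) < 20 || ncol(expr) < 8)
    stop("need >= 20 probes and >= 8 samples to estimate the power")
  a0 <- abs(cor(t(expr)))
  diag(a0) <- 0
  fits <- vapply(powers, function(beta) {
    k <- rowSums(a0^beta)
    scaleFreeFit(k, nBins)
  }, 0)
  tab <- data.frame(power = powers, fit = fits,
                    meanK = vapply(powers, function(beta)
                      mean(rowSums(a0^beta)), 0))
  ok <- which(fits >= rsqCut)
  if (length(ok)) {
    power <- powers[ok[1]]
  } else {
    warning("no power reaches scale-free fit ", rsqCut, "; using default 6")
    power <- 6
  }
  list(power = power, fitTable = tab)
}

#' Scale-free topology fit index
#'
#' Signed R^2 of `log10 p(k)` against `log10 k` over binned connectivities.
#'
#' @param k vector of node connectivities.
#' @param nBins number of bins; default 10.
#' @return signed R-squared (positive when p(k) decreases with k).
#' @export
scaleFreeFit <- function(k, nBins = 10) {
  if (sd(k) == 0 || all(k <= 0)) {
    warning("degenerate connectivity distribution")
    return(0)
  }
  bins <- cut(k, nBins)
  dk <- tapply(k, bins, mean)
  pk <- tapply(k, bins, length) / length(k)
  keep <- !is.na(dk) & dk > 0 & pk > 0
  if (sum(keep) < 3) return(0)
  fit <- stats::lm(log10(pk[keep]) ~ log10(dk[keep]))
  r2 <- summary(fit)$r.squared
  -sign(stats::coef(fit)[2]) * r2
}

#' Topological overlap matrix
#'
#' Unsigned adjacency `a_ij = |cor(x_i, x_j)|^beta` (diagonal 0), then
#' `TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' `TOM_ii = 1`. Symmetric with entries in `[0, 1]`.
#'
#' @param expr numeric matrix, probes x samples.
#' @param beta soft-thresholding power (>= 1).
#' @return the TOM, probes x probes.
#' @export
tomMatrix <- function(expr, beta) {
  stopifnot(beta >= 1)
  if (any(apply(expr, 1, sd) == 0))
    stop("constant probe(s) present; filter before computing the TOM")
  a <- abs(cor(t(expr)))^beta
  diag(a) <- 0
  k <- rowSums(a)
  num <- a %*% a + a
  den <- outer(k, k, pmin) + 1 - a
  tom <- num / den
  diag(tom) <- 1
  dimnames(tom) <- list(rownames(expr), rownames(expr))
  tom
}

#' Detect co-expression modules
#'
#' Average-linkage hierarchical clustering of `1 - TOM`, cut statically at
#' `cutHeight` (default 0.99 x the maximum merge height). Branches smaller
#' than `minSize` become "grey" (unassigned). Modules whose eigengenes
#' correlate at or above `mergeCor` are merged iteratively until stable.
#' Remaining modules are named by the canonical colour sequence in
#' decreasing size order.
#'
#' @param tom topological overlap matrix ([tomMatrix()]).
#' @param expr the expression matrix the TOM was computed from (needed for
#'   eigengene-based merging).
#' @param minSize minimum module size; default 30.
#' @param cutHeight static cut height; default 0.99 x max merge height.
#' @param mergeCor eigengene correlation threshold for merging; default 0.75.
#' @return list with `assignment` (named character vector probe -> module
#'   colour, "grey" = unassigned), `softPower` attribute left to the caller,
#'   `mergeHeight` (cut height used) and `dendro` (the hclust tree).
#' @export
detectModules <- function(tom, expr, minSize = 30, cutHeight = NULL,
                          mergeCor = 0.75) {
  stopifnot(identical(rownames(tom), rownames(expr)))
  d <- 1 - tom
  h <- hclust(as.dist(d), method = "average")
  if (is.null(cutHeight)) cutHeight <- 0.99 * max(h$height)
  cl <- cutree(h, h = cutHeight)
  sizes <- table(cl)
  keep <- names(sizes)[sizes >= minSize]
  lab <- ifelse(cl %in% as.integer(keep), as.character(cl), "grey")
  names(lab) <- rownames(tom)

  ## iterative eigengene merge
  repeat {
    mods <- setdiff(unique(lab), "grey")
    if (length(mods) < 2) break
    mes <- vapply(mods, function(m)
      moduleEigengene(expr[names(lab)[lab == m], , drop = FALSE])$me,
      numeric(ncol(expr)))
    cm <- cor(mes)
    diag(cm) <- 0
    if (max(cm) < mergeCor) break
    ij <- which(cm == max(cm), arr.ind = TRUE)[1, ]
    lab[lab == mods[ij[2]]] <- mods[ij[1]]
  }

  ## rename by decreasing size using the colour convention
  mods <- setdiff(unique(lab), "grey")
  if (length(mods)) {
    sizes <- vapply(mods, function(m) sum(lab == m), 0L)
    ## size ties break on module content (first member probe name), so the
    ## labelling is invariant to probe order
    firstProbe <- vapply(mods, function(m) min(names(lab)[lab == m]), "")
    ord <- mods[order(-sizes, firstProbe)]
    colours <- c(MODULE_COLOURS,
                 sprintf("module%d", seq_len(max(0, length(ord) - length(MODULE_COLOURS)))))
    map <- setNames(colours[seq_along(ord)], ord)
    lab[lab != "grey"] <- map[lab[lab != "grey"]]
  }
  if (!any(lab != "grey"))
    warning("all probes unassigned (grey)")
  list(assignment = lab, mergeHeight = cutHeight, dendro = h)
}

#' Module eigengene
#'
#' First right-singular vector of the per-probe standardized member matrix:
#' one value per sample, unit Euclidean norm, sign-oriented so that it
#' correlates non-negatively with the mean standardized member expression.
#'
#' @param memberExpr numeric matrix, member probes x samples (>= 2 members).
#' @return list with `me` (the eigengene), `varExplained` (fraction of
#'   variance carried by the first component) and `kME` (per-member
#'   correlation with the eigengene).
#' @export
moduleEigengene <- function(memberExpr) {
  if (nrow(memberExpr) < 2) stop("need >= 2 member probes")
  sds <- apply(memberExpr, 1, sd)
  if (any(sds == 0)) {
    warning(sum(sds == 0), " zero-variance member(s) dropped")
    memberExpr <- memberExpr[sds > 0, , drop = FALSE]
    if (nrow(memberExpr) < 2) stop("fewer than 2 members after dropping")
  }
  xs <- t(scale(t(memberExpr)))
  sv <- svd(xs)
  me <- sv$v[, 1]
  if (cor(me, colMeans(xs)) < 0) me <- -me
  names(me) <- colnames(memberExpr)
  list(me = me,
       varExplained = sv$d[1]^2 / sum(sv$d^2),
       kME = cor(t(memberExpr), me)[, 1])
}

#' Eigengenes of all modules
#'
#' @param expr expression matrix, probes x samples.
#' @param assignment named probe -> module vector ([detectModules()]).
#' @return matrix modules x samples of unit-norm eigengenes (grey excluded).
#' @export
moduleEigengenes <- function(expr, assignment) {
  mods <- setdiff(sort(unique(assignment)), "grey")
  mes <- t(vapply(mods, function(m)
    moduleEigengene(expr[names(assignment)[assignment == m], , drop = FALSE])$me,
    numeric(ncol(expr))))
  rownames(mes) <- mods
  colnames(mes) <- colnames(expr)
  mes
}

#' Area under the ROC curve of a score against a binary outcome
#'
#' Rank-statistic (Mann-Whitney) formulation; ties share mid-ranks.
#'
#' @param score numeric scores.
#' @param positive logical vector, TRUE for the positive class.
#' @return AUC in `[0, 1]`.
#' @export
rocAuc <- function(score, positive) {
  positive <- as.logical(positive)
  n1 <- sum(positive)
  n0 <- sum(!positive)
  if (n1 == 0 || n0 == 0) stop("both classes must be non-empty")
  r <- rank(score)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Module metrics
#'
#' For each module eigengene: `modAUC1` (AUC separating the two class
#' levels; the alphabetically later level is the positive one), `modAUC2`
#' (same for the stratification variable), `diffME` (difference of median
#' eigengene value, case minus control) and `sigenrich` (-log10 of the
#' smallest BH q over the designated marker-collection hypergeometric
#' tests; 0 when the module has no test). AUCs are reported unflipped, so
#' values below 0.5 indicate association with the reference level.
#'
#' @param mes modules x samples eigengene matrix ([moduleEigengenes()]).
#' @param se the experiment (for class/stratum assignments).
#' @param enrichment optional enrichment table ([enrichCollection()]) for
#'   the signature collection; used for `sigenrich`.
#' @return data.frame: module, modAUC1, modAUC2, diffME, sigenrich.
#' @export
moduleMetrics <- function(mes, se, enrichment = NULL) {
  md <- S4Vectors::metadata(se)
  ph <- phenoData(se)
  cls <- factor(ph[[md$classVar]])
  strat <- factor(ph[[md$stratVar]])
  if (nlevels(cls) != 2 || nlevels(strat) != 2)
    stop("class and stratification variables must be binary")
  if (any(table(cls) == 0) || any(table(strat) == 0))
    stop("a design level has no samples; metrics undefined")
  pos1 <- as.character(cls) != md$classRef      # non-reference = case
  pos2 <- as.character(strat) != md$stratRef
  out <- data.frame(module = rownames(mes), stringsAsFactors = FALSE)
  out$modAUC1 <- apply(mes, 1, rocAuc, positive = pos1)
  out$modAUC2 <- apply(mes, 1, rocAuc, positive = pos2)
  out$diffME <- apply(mes, 1, function(me)
    median(me[pos1]) - median(me[!pos1]))
  out$sigenrich <- 0
  if (!is.null(enrichment) && nrow(enrichment)) {
    minQ <- tapply(enrichment$q, enrichment$module, min)
    hit <- out$module %in% names(minQ)
    out$sigenrich[hit] <- -log10(pmax(minQ[out$module[hit]], 1e-300))
  }
  out
}

#' Thin intra-module edges by topological overlap
#'
#' Ranks all intra-module probe pairs by TOM (descending) and retains
#' `min(cap, max(1, ceiling(frac * npairs)))` edges — at least the top 10%
#' of module edges, capped at 2000, under the defaults. Ties break
#' lexicographically on the (probe_i, probe_j) pair.
#'
#' @param tom topological overlap matrix.
#' @param members character vector of member probes (>= 2).
#' @param frac fraction of pairs retained; default 0.10.
#' @param cap hard cap on retained edges; default 2000.
#' @return data.frame: probe1, probe2, weight (TOM), ordered as retained.
#' @export
selectModuleEdges <- function(tom, members, frac = 0.10, cap = 2000) {
  stopifnot(length(members) >= 2, all(members %in% rownames(tom)))
  members <- sort(members)
  idx <- t(combn(length(members), 2))
  p1 <- members[idx[, 1]]
  p2 <- members[idx[, 2]]
  w <- tom[cbind(p1, p2)]
  ord <- order(-w, p1, p2)
  n <- min(cap, max(1, ceiling(frac * length(w))))
  keep <- ord[seq_len(n)]
  data.frame(probe1 = p1[keep], probe2 = p2[keep], weight = w[keep],
             stringsAsFactors = FALSE)
}
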