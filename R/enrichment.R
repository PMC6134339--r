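## Hypergeometric list enrichment with BH correction inside each
## (module x collection) family, and the retention/relaxation policy used
## when enumerating enrichment edges.

#' Upper-tail hypergeometric probability
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: drawing `n` genes (the
#' module) from a universe of `N` containing `K` annotated genes, the
#' probability of at least `k` hits.
#'
#' @param k observed overlap.
#' @param n module size (draws).
#' @param K annotation set size in the universe.
#' @param N universe size.
#' @return the exact tail probability.
#' @export
hypergeomP <- function(k, n, K, N) {
  if (k < 0 || n < 0 || K < 0 || N < 1 || k > min(n, K) || n > N || K > N)
    stop("violated hypergeometric bounds (need k <= min(n, K); n, K <= N)")
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Enrichment of modules against an annotation collection
#'
#' Every (module, set) pair is tested by the one-sided hypergeometric test
#' conditional on the universe (the unique symbols measured on the filtered
#' array); p-values are BH-corrected within each module x collection
#' family. Per module, sets with q < `qCut` are retained ranked by p,
#' truncated at `maxKeep`. If fewer than `minKeep` pass, the criterion is
#' relaxed: the top `minKeep` sets by nominal p with p < `pCut` are
#' retained, and those not q-significant are flagged `relaxed`. If nothing
#' reaches nominal significance, nothing is retained. The q-value is kept
#' on every retained result either way.
#'
#' @param modules named list of symbol vectors (the gene modules).
#' @param collection named list of symbol vectors (the annotation sets).
#' @param universe character vector of measured symbols.
#' @param qCut BH-corrected cutoff; default 0.05.
#' @param pCut nominal cutoff used by the relaxation path; default 0.05.
#' @param minKeep minimum retained per module before relaxing; default 3.
#' @param maxKeep maximum retained per module; default 10.
#' @return data.frame: module, set, k, n, K, N, p, q, relaxed, retained.
#' @export
enrichCollection <- function(modules, collection, universe, qCut = 0.05,
                             pCut = 0.05, minKeep = 3, maxKeep = 10) {
  universe <- unique(universe)
  N <- length(universe)
  if (N == 0) stop("empty universe")
  collU <- lapply(collection, function(s) intersect(unique(s), universe))
  out <- list()
  for (m in names(modules)) {
    mod <- intersect(unique(modules[[m]]), universe)
    n <- length(mod)
    df <- data.frame(module = m, set = names(collection),
                     k = vapply(collU, function(s) length(intersect(s, mod)), 0L),
                     n = n,
                     K = vapply(collU, length, 0L),
                     N = N, stringsAsFactors = FALSE)
    df$p <- mapply(hypergeomP, df$k, df$n, df$K, df$N)
    df$q <- bhAdjust(df$p)
    sig <- which(df$q < qCut)
    if (length(sig) >= minKeep) {
      keep <- sig[order(df$p[sig], df$set[sig])]
      keep <- keep[seq_len(min(maxKeep, length(keep)))]
      df$relaxed <- FALSE
      df$retained <- seq_len(nrow(df)) %in% keep
    } else {
      nom <- which(df$p < pCut)
      keep <- nom[order(df$p[nom], df$set[nom])]
      keep <- keep[seq_len(min(minKeep, length(keep)))]
      df$retained <- seq_len(nrow(df)) %in% keep
      df$relaxed <- df$retained & !(df$q < qCut)
    }
    out[[m]] <- df
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
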