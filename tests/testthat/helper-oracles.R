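## Independent oracles used across the suite. These deliberately avoid the
## package's own code paths.

## brute-force topological overlap (triple loop)
bruteTOM <- function(expr, beta) {
  a <- abs(cor(t(expr)))^beta
  diag(a) <- 0
  n <- nrow(a)
  k <- rowSums(a)
  tom <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) { tom[i, j] <- 1; next }
    l <- 0
    for (u in seq_len(n)) l <- l + a[i, u] * a[u, j]
    tom[i, j] <- (l + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
  }
  dimnames(tom) <- dimnames(a)
  tom
}

## exhaustive concordant-pair AUC
bruteAUC <- function(score, positive) {
  pos <- score[positive]
  neg <- score[!positive]
  tot <- 0
  for (p in pos) for (n in neg)
    tot <- tot + (p > n) + 0.5 * (p == n)
  tot / (length(pos) * length(neg))
}

## step-up BH from the definition
bhOracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- rep(NA_real_, m)
  qs <- p[o] * m / seq_len(m)
  qs <- rev(cummin(rev(qs)))
  q[o] <- pmin(qs, 1)
  q
}

## hypergeometric upper tail by explicit term summation
hyperOracle <- function(k, n, K, N) {
  kk <- k:min(n, K)
  sum(choose(K, kk) * choose(N - K, n - kk)) / choose(N, n)
}

## brute-force path-pattern enumeration over the exported tables
brutePaths <- function(graph, query) {
  if (is.character(query)) query <- parsePattern(query)
  nodes <- graphNodes(graph)
  edges <- graphEdges(graph)
  test <- function(props, preds) {
    for (pr in preds) {
      v <- props[[pr$prop]]
      if (is.null(v)) return(FALSE)
      ok <- switch(pr$op, "=" = v == pr$value, "!=" = v != pr$value,
                   ">" = v > pr$value, "<" = v < pr$value,
                   ">=" = v >= pr$value, "<=" = v <= pr$value)
      if (!isTRUE(ok)) return(FALSE)
    }
    TRUE
  }
  nodeOk <- function(key, cons) {
    i <- match(key, nodes$key)
    nodes$label[i] == cons$label && test(nodes$props[[i]], cons$preds)
  }
  out <- list()
  recurse <- function(path, depth) {
    if (depth == length(query$nodes)) {
      out[[length(out) + 1]] <<- path
      return(invisible())
    }
    cons <- query$edges[[depth]]
    cur <- path[length(path)]
    for (i in seq_len(nrow(edges))) {
      other <- if (edges$src[i] == cur) edges$dst[i]
               else if (edges$dst[i] == cur) edges$src[i]
               else next
      if (!is.null(cons$type) && edges$type[i] != cons$type) next
      if (!test(edges$props[[i]], cons$preds)) next
      if (other %in% path) next
      if (!nodeOk(other, query$nodes[[depth + 1]])) next
      recurse(c(path, other), depth + 1)
    }
  }
  for (key in nodes$key[vapply(nodes$key, nodeOk, TRUE,
                               cons = query$nodes[[1]])])
    recurse(key, 1)
  out[order(vapply(out, paste, "", collapse = "\x1f"))]
}
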