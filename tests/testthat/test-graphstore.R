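test_that("MERGE is idempotent on nodes and overlays properties", {
  g <- emptyGraph()
  g <- mergeNode(g, "SYMBOL", "TNF")
  g <- mergeNode(g, "SYMBOL", "TNF")
  expect_identical(nodeCount(g), 1L)
  g <- mergeNode(g, "SYMBOL", "TNF", props = list(score = 1, keep = "yes"))
  g <- mergeNode(g, "SYMBOL", "TNF", props = list(logfc = 2.5))
  pr <- nodeProps(g, nodeKey("SYMBOL", "TNF"))
  expect_equal(pr$logfc, 2.5)
  expect_equal(pr$score, 1)
  expect_equal(pr$keep, "yes")
  ## same name, different dataset scope: distinct identity
  g <- mergeNode(g, "wgcna", "blue", square = "ds1", edge = "1")
  g <- mergeNode(g, "wgcna", "blue", square = "ds2", edge = "1")
  expect_identical(nodeCount(g), 3L)
  expect_error(mergeNode(g, "gene", "x"), "unknown node label")
})

test_that("edge identity is (endpoints, type, graph index) and endpoints auto-create", {
  a <- nodeKey("PROBE", "p1", "d", "1")
  b <- nodeKey("SYMBOL", "s1")
  g <- emptyGraph()
  g <- mergeEdge(g, a, b, "mapping", 2)
  g <- mergeEdge(g, a, b, "mapping", 2)
  expect_identical(edgeCount(g), 1L)
  expect_identical(nodeCount(g), 2L)      # endpoints created implicitly
  g <- mergeEdge(g, a, b, "correlation", 4, props = list(weight = 0.5))
  expect_identical(edgeCount(g), 2L)      # type is part of identity
  g <- mergeEdge(g, a, b, "correlation", 4, props = list(weight = 0.9))
  expect_identical(edgeCount(g), 2L)
  expect_equal(graphEdges(g)$props[[2]]$weight, 0.9)
  expect_error(mergeEdge(g, a, b, "friendship", 1), "unknown edge type")
})

test_that("graph union is associative, idempotent, and shares nodes by key", {
  mkg <- function(sym, w) {
    g <- emptyGraph()
    g <- mergeNode(g, "SYMBOL", "shared", props = list(from = sym))
    g <- mergeNode(g, "wgcna", sym, "d", "1")
    mergeEdge(g, nodeKey("wgcna", sym, "d", "1"), nodeKey("SYMBOL", "shared"),
              "mapping", w)
  }
  A <- mkg("a", 1); B <- mkg("b", 2); C <- mkg("c", 3)
  u1 <- graphUnion(list(graphUnion(list(A, B)), C))
  u2 <- graphUnion(list(A, graphUnion(list(B, C))))
  expect_setequal(graphNodes(u1)$key, graphNodes(u2)$key)
  expect_setequal(graphEdges(u1)$key, graphEdges(u2)$key)
  expect_identical(nodeCount(u1), 4L)     # one shared SYMBOL + three modules
  ## idempotence
  uu <- graphUnion(list(u1, u1))
  expect_identical(nodeCount(uu), nodeCount(u1))
  expect_identical(edgeCount(uu), edgeCount(u1))
  ## neutral element
  expect_identical(nodeCount(graphUnion(list(u1, emptyGraph()))),
                   nodeCount(u1))
  ## randomized MERGE idempotence
  set.seed(60)
  g <- emptyGraph()
  for (i in 1:50) {
    lbl <- sample(c("PROBE", "SYMBOL", "pheno"), 1)
    g <- mergeNode(g, lbl, paste0("n", sample(20, 1)),
                   props = list(v = runif(1)))
  }
  before <- nodeCount(g)
  g2 <- graphUnion(list(g, g))
  expect_identical(nodeCount(g2), before)
})

test_that("pattern matching equals brute-force enumeration on a random graph", {
  set.seed(61)
  g <- emptyGraph()
  nPheno <- 8; nW <- 12; nP <- 60; nS <- 40
  for (i in seq_len(nPheno)) g <- mergeNode(g, "pheno", paste0("ph", i), "d", "1")
  for (i in seq_len(nW)) g <- mergeNode(g, "wgcna", paste0("w", i), "d", "1")
  for (i in seq_len(nP))
    g <- mergeNode(g, "PROBE", paste0("p", i), "d", "1",
                   props = list(logfc = round(rnorm(1, 0, 2), 2)))
  for (i in seq_len(nS)) g <- mergeNode(g, "SYMBOL", paste0("s", i))
  ## random sparse edges
  for (i in 1:40)
    g <- mergeEdge(g, nodeKey("pheno", paste0("ph", sample(nPheno, 1)), "d", "1"),
                   nodeKey("wgcna", paste0("w", sample(nW, 1)), "d", "1"),
                   "correlation", 29,
                   props = list(weight = round(runif(1, -1, 1), 2)))
  for (i in 1:120)
    g <- mergeEdge(g, nodeKey("PROBE", paste0("p", sample(nP, 1)), "d", "1"),
                   nodeKey("wgcna", paste0("w", sample(nW, 1)), "d", "1"),
                   "mapping", 3)
  for (i in seq_len(nP))
    g <- mergeEdge(g, nodeKey("PROBE", paste0("p", i), "d", "1"),
                   nodeKey("SYMBOL", paste0("s", sample(nS, 1))), "mapping", 2)
  q <- "(pheno)-[weight>0.3]-(wgcna)-[]-(PROBE{logfc>0.5})-[]-(SYMBOL)"
  res <- matchPattern(g, q)
  expect_identical(lapply(res$paths, unname), brutePaths(g, q))
  ## unsatisfiable label sequence
  expect_length(matchPattern(g, "(CELL)-[]-(wgcna)")$paths, 0)
  ## subgraph contains exactly the nodes and edges on matched paths
  if (length(res$paths)) {
    expect_setequal(graphNodes(res$subgraph)$key, unique(unlist(res$paths)))
    expect_setequal(graphEdges(res$subgraph)$key, unique(unlist(res$edgeKeys)))
  }
})

test_that("predicates on missing properties fail the candidate without error", {
  g <- emptyGraph()
  g <- mergeNode(g, "PROBE", "p1", props = list(logfc = 3))
  g <- mergeNode(g, "PROBE", "p2")              # no logfc property
  g <- mergeNode(g, "SYMBOL", "s")
  g <- mergeEdge(g, nodeKey("PROBE", "p1"), nodeKey("SYMBOL", "s"), "mapping", 2)
  g <- mergeEdge(g, nodeKey("PROBE", "p2"), nodeKey("SYMBOL", "s"), "mapping", 2)
  expect_message(res <- matchPattern(g, "(PROBE{logfc>1})-[]-(SYMBOL)"),
                 "missing property")
  expect_length(res$paths, 1)
})

test_that("exports are deterministic and GraphML round-trips identically", {
  g <- toyGraphFixture()
  dir <- withr::local_tempdir()
  ## cypher export is byte-identical across runs
  f1 <- file.path(dir, "a.cypher"); f2 <- file.path(dir, "b.cypher")
  exportGraph(g, "cypher", f1)
  exportGraph(g, "cypher", f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_true(any(grepl("^MERGE", readLines(f1))))
  ## tsv pair row counts match the graph
  exportGraph(g, "tsv_pair", file.path(dir, "g"))
  nd <- read.delim(file.path(dir, "g.nodes.tsv"))
  ed <- read.delim(file.path(dir, "g.edges.tsv"))
  expect_identical(nrow(nd), nodeCount(g))
  expect_identical(nrow(ed), edgeCount(g))
  ## graphml round trip preserves keys and property maps
  gm <- file.path(dir, "g.graphml")
  exportGraph(g, "graphml", gm)
  back <- importGraphML(gm)
  expect_setequal(graphNodes(back)$key, graphNodes(g)$key)
  expect_setequal(graphEdges(back)$key, graphEdges(g)$key)
  for (key in graphNodes(g)$key) {
    a <- nodeProps(g, key); b <- nodeProps(back, key)
    expect_identical(a[sort(names(a))], b[sort(names(b))])
  }
  ## a query against the re-import gives the same answer
  q <- "(pheno)-[weight>0.6]-(wgcna)-[]-(PROBE{logfc>2})-[]-(SYMBOL)"
  expect_identical(lapply(matchPattern(back, q)$paths, unname),
                   lapply(matchPattern(g, q)$paths, unname))
})
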