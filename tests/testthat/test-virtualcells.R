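## constructed micro-fixture: 2 modules, 2 cells, hand-set enrichment
.linkFixture <- function() {
  set.seed(80)
  n <- 24
  prop1 <- runif(n, 0.2, 0.8)
  mes <- rbind(corr = scale(prop1)[, 1],            # tracks cell 1 exactly
               uncor = rnorm(n))
  colnames(mes) <- paste0("S", 1:n)
  proportions <- cbind(cellA = prop1, cellB = 1 - prop1)
  rownames(proportions) <- colnames(mes)
  enr <- data.frame(module = c("corr", "uncor"),
                    set = c("cellA.xp1", "cellB.xp1"),
                    k = 5, n = 10, K = 10, N = 100,
                    p = 1e-6, q = 1e-5, relaxed = FALSE, retained = TRUE)
  map <- c(cellA.xp1 = "cellA", cellB.xp1 = "cellB",
           cellA = "cellA", cellB = "cellB")
  list(mes = mes, proportions = proportions, enr = enr, map = map)
}

test_that("module-cell links require correlation AND marker enrichment", {
  f <- .linkFixture()
  links <- linkModulesToCells(f$mes, f$proportions, f$enr, f$map)
  ## corr-cellA: both conditions met
  expect_true(any(links$module == "corr" & links$cell == "cellA"))
  ## corr-cellB: correlation passes (anti-correlated proportions) but the
  ## enrichment for cellB belongs to the other module -> no link
  expect_false(any(links$module == "corr" & links$cell == "cellB"))
  ## uncor-cellB: enrichment present but no correlation -> no link
  expect_false(any(links$module == "uncor", na.rm = TRUE) &&
                 any(links$module == "uncor" & links$cell == "cellB"))
  ## dropping the enrichment removes the link (conjunction law)
  links2 <- linkModulesToCells(f$mes, f$proportions,
                               f$enr[f$enr$module != "corr", ], f$map)
  expect_false(any(links2$module == "corr"))
})

test_that("virtual cells union linked module probes and carry DE overlays", {
  f <- .linkFixture()
  links <- data.frame(module = c("m1", "m2"), cell = "cellA",
                      R = 0.9, corQ = 1e-4, enrichQ = 1e-4)
  assignment <- c(P1 = "m1", P2 = "m1", P3 = "m2", P4 = "m2", P5 = "grey",
                  P6 = "m3")
  set.seed(81)
  x <- matrix(rnorm(6 * 10), 6, 10,
              dimnames = list(paste0("P", 1:6), paste0("S", 1:10)))
  se <- tinyExperiment(x, class = rep(c("case", "control"), 5),
                       sex = rep(c("F", "M"), 5))
  de <- data.frame(probe = paste0("P", 1:6), logfc = 1:6 / 2,
                   q = rep(0.01, 6))
  pw <- data.frame(module = "m1", set = "path1", q = 1e-3, retained = TRUE)
  vc <- buildVirtualCell(links, assignment, se, de, pw, "cellA")
  expect_setequal(vc$probes, c("P1", "P2", "P3", "P4"))
  expect_identical(vc$modules, c("m1", "m2"))
  expect_true(isSymmetric(vc$coexpression))
  expect_equal(unname(diag(vc$coexpression)), rep(1, 4))
  ## DE overlay equals the DE table entries for the same probes
  expect_equal(vc$de$logfc[vc$de$probe == "P3"], 1.5)
  expect_error(buildVirtualCell(links, assignment, se, de, pw, "cellX"),
               "available")
})

test_that("activity entries average up and down log fold changes separately", {
  vc <- structure(list(cell = "cellA", modules = "m1",
                       probes = c("P1", "P2", "P3"), coexpression = NULL,
                       pathways = NULL, de = NULL), class = "VirtualCell")
  de <- data.frame(probe = paste0("P", 1:4), logfc = c(1, 3, -1, 9),
                   q = rep(0.01, 4))
  p2s <- setNames(paste0("G", 1:4), paste0("P", 1:4))
  pathways <- list(pw1 = c("G1", "G2"),          # both up: mean 2
                   pw2 = c("G1", "G3"),          # one up, one down
                   pw3 = "G4")                   # not in the virtual cell
  act <- cellPathwayActivity(list(vc), pathways, de, p2s)
  expect_equal(act$score[act$pathway == "pw1" & act$direction == "up"], 2)
  expect_equal(act$score[act$pathway == "pw2" & act$direction == "up"], 1)
  expect_equal(act$score[act$pathway == "pw2" & act$direction == "down"], -1)
  ## no mixing of signs; absent combinations stay absent
  expect_true(all(act$score[act$direction == "up"] >= 0))
  expect_true(all(act$score[act$direction == "down"] <= 0))
  expect_false("pw3" %in% act$pathway)
})

test_that("activity rankings equal independent re-aggregation", {
  set.seed(82)
  act <- expand.grid(cell_instance = paste0("c", 1:4),
                     pathway = paste0("pw", 1:6),
                     direction = c("up", "down"),
                     stringsAsFactors = FALSE)
  act$score <- ifelse(act$direction == "up", runif(nrow(act)), -runif(nrow(act)))
  act <- act[sample(nrow(act), 40), ]
  act$cell <- act$cell_instance
  r <- rankActivity(act)
  for (d in c("up", "down")) {
    sub <- act[act$direction == d, ]
    tp <- tapply(sub$score, sub$pathway, sum)
    oracle <- sort(setNames(as.numeric(tp), names(tp)))
    mine <- r$pathways[r$pathways$direction == d, ]
    expect_equal(sort(setNames(mine$total, mine$name)), oracle,
                 tolerance = 1e-12)
  }
  ## ranking invariant under row permutation
  r2 <- rankActivity(act[sample(nrow(act)), ])
  expect_identical(r, r2)
})

test_that("cross-dataset cell comparison clusters identical profiles together", {
  a1 <- data.frame(cell_instance = "1_cd8", cell = "cd8",
                   pathway = paste0("pw", 1:4), direction = "up",
                   score = c(1, 2, 3, 4), n_probes = 2)
  a2 <- a1                      # identical activity in dataset 2
  a3 <- a1; a3$score <- -a1$score; a3$direction <- "down"
  res <- metaCellCompare(list(dsA = a1, dsB = a2, dsC = a3), cellFilter = "cd8")
  expect_identical(ncol(res$matrix), 3L)
  ## identical vectors have distance zero and sit adjacent after clustering
  d <- as.matrix(dist(t(replace(res$matrix, is.na(res$matrix), 0))))
  pairAB <- d["dsA_1_cd8", "dsB_1_cd8"]
  expect_equal(unname(pairAB), 0)
  ord <- res$order
  expect_equal(abs(which(ord == "dsA_1_cd8") - which(ord == "dsB_1_cd8")), 1)
  ## missing entries are NA in the matrix (absent, not zero)
  expect_true(any(is.na(res$matrix)))
  expect_error(metaCellCompare(list(x = a1, y = a2), cellFilter = "nomatch"),
               "matches no")
})
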