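test_that("TOM obeys its boundary algebra and matches the brute-force oracle", {
  ## uncorrelated probes: TOM off-diagonal ~ 0 relative to adjacency
  set.seed(10)
  x <- twoBlockExpr(n = 30, perBlock = 10, rho = 0.9)
  tom <- tomMatrix(x, 6)
  expect_true(isSymmetric(tom))
  expect_equal(unname(diag(tom)), rep(1, nrow(tom)))
  expect_true(all(tom >= 0 & tom <= 1 + 1e-12))
  ## brute-force equality on a random 20-probe instance
  y <- matrix(rnorm(20 * 15), 20, 15,
              dimnames = list(sprintf("P%02d", 1:20), sprintf("S%02d", 1:15)))
  for (beta in c(1, 6)) {
    expect_equal(tomMatrix(y, beta), bruteTOM(y, beta), tolerance = 1e-12)
  }
  ## complete graph (all |cor| = 1): TOM is exactly 1 everywhere
  z <- matrix(rnorm(8), 1, 8)[rep(1, 5), ]
  z <- z * (1:5)            # scaled copies keep |cor| = 1
  dimnames(z) <- list(paste0("P", 1:5), paste0("S", 1:8))
  tomC <- tomMatrix(z, 3)
  expect_equal(unname(tomC), matrix(1, 5, 5), tolerance = 1e-12)
  ## constant probes are rejected
  z2 <- rbind(z, const = rep(1, 8))
  expect_error(tomMatrix(z2, 3), "constant")
})

test_that("zero adjacency gives zero topological overlap off the diagonal", {
  ## explicitly orthogonal rows: exact zero pairwise correlations
  x <- rbind(c(1, 1, -1, -1), c(1, -1, 1, -1), c(1, -1, -1, 1))
  dimnames(x) <- list(paste0("P", 1:3), paste0("S", 1:4))
  tom <- tomMatrix(x, 2)
  expect_equal(unname(tom), diag(3), tolerance = 1e-12)
})

test_that("soft power selection matches an independent re-implementation", {
  run <- defaultRun()
  x <- run$x
  sp <- pickSoftPower(x)
  ## oracle: same declared criterion, separate code
  a0 <- abs(cor(t(x)))
  diag(a0) <- 0
  pick <- NA
  for (beta in 1:20) {
    k <- rowSums(a0^beta)
    bins <- cut(k, 10)
    dk <- tapply(k, bins, mean)
    pk <- as.numeric(table(bins)) / length(k)
    ok <- !is.na(dk) & dk > 0 & pk > 0
    fit <- lm(log10(pk[ok]) ~ log10(dk[ok]))
    r2 <- -sign(coef(fit)[2]) * summary(fit)$r.squared
    if (r2 >= 0.8) { pick <- beta; break }
  }
  expect_identical(sp$power, pick)
  ## determinism
  expect_identical(pickSoftPower(x)$power, sp$power)
  ## unreachable threshold falls back to the declared default of 6
  expect_warning(p6 <- pickSoftPower(x, rsqCut = 1.0001)$power, "default 6")
  expect_identical(p6, 6)
})

test_that("module detection recovers planted orthogonal modules exactly", {
  x <- twoBlockExpr(n = 40, perBlock = 30, rho = 0.95, seed = 13)
  ## add unstructured background
  set.seed(14)
  bg <- matrix(rnorm(40 * 40), 40, 40,
               dimnames = list(sprintf("N%03d", 1:40), colnames(x)))
  xx <- rbind(x, bg)
  tom <- tomMatrix(xx, 6)
  det <- detectModules(tom, xx, minSize = 10)
  truth <- c(rep("m1", 30), rep("m2", 30), rep("noise", 40))
  mods <- setdiff(unique(det$assignment), "grey")
  expect_length(mods, 2)
  expect_equal(mclust::adjustedRandIndex(
    truth[truth != "noise"], det$assignment[truth != "noise"]), 1.0)
  ## labels follow the colour convention by size
  expect_setequal(mods, c("turquoise", "blue"))
  ## min_size larger than the probe count sends everything to grey
  expect_warning(all_grey <- detectModules(tom, xx, minSize = 1000), "grey")
  expect_true(all(all_grey$assignment == "grey"))
})

test_that("modules driven by one latent factor are merged", {
  set.seed(15)
  n <- 40
  z <- rnorm(n)
  mk <- function(m, sdn) t(vapply(seq_len(m), function(i)
    z + rnorm(n, 0, sdn), numeric(n)))
  x <- rbind(mk(20, 0.3), mk(20, 0.3))
  dimnames(x) <- list(sprintf("P%03d", 1:40), sprintf("S%02d", 1:n))
  tom <- tomMatrix(x, 6)
  det <- detectModules(tom, x, minSize = 10, mergeCor = 0.75)
  expect_length(setdiff(unique(det$assignment), "grey"), 1)
})

test_that("module detection is stable under probe order permutation", {
  x <- twoBlockExpr(n = 30, perBlock = 15, rho = 0.9, seed = 16)
  tom <- tomMatrix(x, 6)
  det1 <- detectModules(tom, x, minSize = 5)
  set.seed(17)
  perm <- sample(nrow(x))
  xp <- x[perm, ]
  tomp <- tomMatrix(xp, 6)
  det2 <- detectModules(tomp, xp, minSize = 5)
  expect_identical(det1$assignment[rownames(x)], det2$assignment[rownames(x)])
})

test_that("the eigengene is the unit-norm leading component, sign-oriented", {
  set.seed(18)
  base <- rnorm(25)
  x <- t(vapply(1:6, function(i) 2 * base + 5, numeric(25)))
  dimnames(x) <- list(paste0("P", 1:6), paste0("S", 1:25))
  me <- moduleEigengene(x)
  expect_equal(sum(me$me^2), 1, tolerance = 1e-12)
  expect_equal(abs(cor(me$me, base)), 1, tolerance = 1e-12)
  expect_gte(cor(me$me, colMeans(t(scale(t(x))))), 0)
  expect_equal(me$varExplained, 1, tolerance = 1e-12)
  ## sign law holds across random modules
  for (i in 1:20) {
    y <- matrix(rnorm(8 * 15), 8, 15)
    dimnames(y) <- list(paste0("P", 1:8), paste0("S", 1:15))
    m <- moduleEigengene(y)
    expect_gte(cor(m$me, colMeans(t(scale(t(y))))), 0)
  }
  ## zero-variance member dropped with a warning
  x2 <- rbind(x, const = rep(1, 25))
  expect_warning(moduleEigengene(x2), "zero-variance")
})

test_that("a low-noise planted module concentrates variance on its eigengene", {
  set.seed(19)
  z <- rnorm(30)
  x <- t(vapply(1:20, function(i) z + rnorm(30, 0, 0.1), numeric(30)))
  dimnames(x) <- list(paste0("P", 1:20), paste0("S", 1:30))
  expect_gte(moduleEigengene(x)$varExplained, 0.8)
})

test_that("AUC via ranks equals exhaustive pair counting", {
  expect_equal(rocAuc(c(1, 2, 3, 4), c(FALSE, FALSE, TRUE, TRUE)), 1.0)
  expect_equal(rocAuc(c(3, 1, 2, 4), c(FALSE, FALSE, TRUE, TRUE)), 3 / 4)
  set.seed(20)
  for (i in 1:30) {
    n <- sample(5:50, 1)
    score <- sample(1:10, n, replace = TRUE)   # ties included
    pos <- runif(n) < 0.5
    if (!any(pos) || all(pos)) next
    expect_equal(rocAuc(score, pos), bruteAUC(score, pos), tolerance = 1e-12)
  }
  expect_error(rocAuc(1:3, c(TRUE, TRUE, TRUE)), "non-empty")
})

test_that("module metrics report AUCs, eigengene shifts and enrichment strength", {
  mes <- rbind(sep = c(1, 2, 3, 4), mixed = c(3, 1, 2, 4))
  colnames(mes) <- paste0("S", 1:4)
  x <- matrix(rnorm(8), 2, 4, dimnames = list(c("P1", "P2"), colnames(mes)))
  se <- tinyExperiment(x, class = c("control", "control", "case", "case"),
                       sex = c("F", "M", "F", "M"))
  met <- moduleMetrics(mes, se)
  expect_equal(met$modAUC1[met$module == "sep"], 1.0)
  expect_equal(met$modAUC1[met$module == "mixed"], 3 / 4)
  expect_equal(met$diffME[met$module == "sep"], 3.5 - 1.5)
  ## equal medians give diffME 0
  mes0 <- rbind(flat = c(1, 2, 1, 2))
  colnames(mes0) <- colnames(mes)
  expect_equal(moduleMetrics(mes0, se)$diffME, 0)
  ## sigenrich is -log10 of the best q in the designated collection
  enr <- data.frame(module = "sep", set = "s1", q = 1e-4)
  expect_equal(moduleMetrics(mes, se, enrichment = enr)$sigenrich,
               c(4, 0))
})

test_that("edge thinning keeps ceil(10%) of pairs with a hard cap of 2000", {
  run <- defaultRun()
  tom <- run$tom
  ## 250 members -> 31125 pairs -> ceil(3112.5) = 3113 > cap -> 2000
  m250 <- rownames(tom)[1:250]
  expect_identical(nrow(selectModuleEdges(tom, m250)), 2000L)
  ## 10 members -> 45 pairs -> 5 edges
  m10 <- rownames(tom)[1:10]
  e10 <- selectModuleEdges(tom, m10)
  expect_identical(nrow(e10), 5L)
  ## the retained edges are the top-TOM pairs
  pairW <- sort(tom[t(combn(m10, 2))], decreasing = TRUE)
  expect_equal(sort(e10$weight, decreasing = TRUE), pairW[1:5])
  ## 2 members -> single edge
  expect_identical(nrow(selectModuleEdges(tom, rownames(tom)[1:2])), 1L)
})
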