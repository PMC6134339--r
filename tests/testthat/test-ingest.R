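test_that("inputs are aligned on shared samples in expression order", {
  dir <- withr::local_tempdir()
  expr <- matrix(runif(20, 10, 100), 5, 4,
                 dimnames = list(paste0("P", 1:5), paste0("S", 1:4)))
  write.table(data.frame(probe_id = rownames(expr), expr),
              file.path(dir, "e.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  ph <- data.frame(sample_id = paste0("S", 1:4),
                   class = c("a", "a", "b", "b"), sex = c("F", "M", "F", "M"))
  write.csv(ph, file.path(dir, "p.csv"), row.names = FALSE, quote = FALSE)
  res <- readInputs(list(expression = file.path(dir, "e.tsv"),
                         pheno = file.path(dir, "p.csv")),
                    classVar = "class", stratVar = "sex")
  expect_identical(colnames(exprs(res$se)), paste0("S", 1:4))

  ## one extra phenotype sample is dropped with a warning
  ph2 <- rbind(ph, data.frame(sample_id = "S9", class = "a", sex = "F"))
  write.csv(ph2, file.path(dir, "p2.csv"), row.names = FALSE, quote = FALSE)
  expect_warning(
    res2 <- readInputs(list(expression = file.path(dir, "e.tsv"),
                            pheno = file.path(dir, "p2.csv")),
                       classVar = "class", stratVar = "sex"),
    "dropped")
  expect_identical(colnames(exprs(res2$se)), paste0("S", 1:4))

  ## duplicate probe ids are fatal and name the probe
  writeLines(c("probe_id\tS1", "P1\t3", "P1\t4"), file.path(dir, "dup.tsv"))
  expect_error(readExpression(file.path(dir, "dup.tsv")), "P1")

  ## no shared samples is fatal
  ph3 <- data.frame(sample_id = c("X1", "X2"), class = c("a", "b"),
                    sex = c("F", "M"))
  write.csv(ph3, file.path(dir, "p3.csv"), row.names = FALSE, quote = FALSE)
  expect_error(readInputs(list(expression = file.path(dir, "e.tsv"),
                               pheno = file.path(dir, "p3.csv")),
                          classVar = "class", stratVar = "sex"),
               "no shared sample")
})

test_that("unparseable GMT lines fail with the line number", {
  f <- withr::local_tempfile(lines = c("ok\tdesc\tG1\tG2", "bad\tonly-desc"))
  expect_error(readGMT(f), "line 2")
})

test_that("quantile normalization equalizes column distributions", {
  x <- matrix(c(1, 2, 3, 2, 4, 6), 3, 2,
              dimnames = list(paste0("P", 1:3), c("S1", "S2")))
  se <- tinyExperiment(x, class = c("case", "control"), sex = c("F", "M"),
                       normalized = FALSE)
  out <- exprs(normalizeExpression(se))
  ## each output column's sorted vector is the mean of the sorted
  ## log2(x+1) columns
  target <- rowMeans(cbind(sort(log2(x[, 1] + 1)), sort(log2(x[, 2] + 1))))
  expect_equal(sort(out[, 1]), target, ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(sort(out[, 2]), target, ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("normalization is idempotent on column distributions and flags state", {
  set.seed(1)
  x <- matrix(rexp(200, 1 / 50), 20, 10,
              dimnames = list(sprintf("P%02d", 1:20), sprintf("S%02d", 1:10)))
  se <- tinyExperiment(x, class = rep(c("case", "control"), 5),
                       sex = rep(c("F", "M"), each = 5), normalized = FALSE)
  n1 <- normalizeExpression(se)
  s1 <- apply(exprs(n1), 2, sort)
  expect_true(all(abs(s1 - s1[, 1]) < 1e-12))
  expect_true(isNormalized(n1))
  expect_error(normalizeExpression(n1), "already normalized")
  ## values <= 0 are shifted, not rejected
  x2 <- x; x2[1, 1] <- -5
  se2 <- tinyExperiment(x2, class = rep(c("case", "control"), 5),
                        sex = rep(c("F", "M"), each = 5), normalized = FALSE)
  expect_silent(normalizeExpression(se2))
})

test_that("variance filter drops constants and q = 0 keeps everything", {
  set.seed(2)
  x <- rbind(matrix(rnorm(190), 19, 10), const = rep(3, 10))
  rownames(x) <- c(sprintf("P%02d", 1:19), "const")
  colnames(x) <- sprintf("S%02d", 1:10)
  se <- tinyExperiment(x, class = rep(c("case", "control"), 5),
                       sex = rep(c("F", "M"), each = 5))
  filt <- filterProbes(se, "variance", q = 0.5)
  expect_false("const" %in% rownames(exprs(filt)))
  expect_identical(nrow(exprs(filterProbes(se, "variance", q = 0))), 20L)
  ## retained probes keep their original order
  expect_identical(rownames(exprs(filt)),
                   intersect(rownames(x), rownames(exprs(filt))))
})

test_that("factorial filter retains all probes carrying a planted class effect", {
  set.seed(3)
  n <- 40
  class <- rep(c("case", "control"), each = n / 2)
  sex <- rep(c("F", "M"), n / 2)
  x <- matrix(rnorm(100 * n), 100, n,
              dimnames = list(sprintf("P%03d", 1:100), sprintf("S%02d", 1:n)))
  truthIdx <- 1:30
  x[truthIdx, class == "case"] <- x[truthIdx, class == "case"] + 2
  se <- tinyExperiment(x, class, sex)
  filt <- filterProbes(se, "factorial")
  expect_true(all(rownames(x)[truthIdx] %in% rownames(exprs(filt))))
  ## the cap binds
  filt2 <- filterProbes(se, "factorial", nMax = 10)
  expect_identical(nrow(exprs(filt2)), 10L)
  expect_error(filterProbes(se, "variance", q = 0.999), "fewer than 10")
})
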