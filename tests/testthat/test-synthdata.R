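test_that("generator output respects the mixture model and its invariants", {
  cfg <- synthConfig(nSamplesPerStratum = 4, nNoiseProbes = 50, seed = 3)
  ds <- generateDataset(cfg)
  expect_true(all(ds$expr > 0))
  expect_equal(unname(rowSums(ds$truth$proportions)),
               rep(1, nrow(ds$truth$proportions)), tolerance = 1e-9)
  ## marker probes belong to exactly one cell type
  allMarkers <- unlist(ds$truth$markerSets)
  expect_false(anyDuplicated(allMarkers) > 0)
  ## phenotype structure: two factors + numeric covariates
  expect_setequal(unique(ds$pheno$class), c("case", "control"))
  expect_setequal(unique(ds$pheno$sex), c("F", "M"))
  expect_true(is.numeric(ds$pheno$activity_score) && is.numeric(ds$pheno$age))
  ## the designated covariate tracks the disease module's latent factor
  expect_gte(cor(ds$pheno$activity_score, ds$truth$latentFactors[, 1]), 0.8)
})

test_that("noiseless, effect-free expression equals the pure mixture", {
  cfg <- synthConfig(nSamplesPerStratum = 3, nCelltypes = 3,
                     nMarkersPerCell = 5, nPlantedModules = 1,
                     moduleSize = 10, nNoiseProbes = 10, diseaseEffect = 0,
                     sexEffect = 0, markerClassLoading = 0,
                     moduleLatentSd = 0, noiseSd = 0, seed = 2)
  ds <- generateDataset(cfg)
  expected <- t(ds$truth$signature) %*% t(ds$truth$proportions)
  expect_equal(ds$expr, expected, tolerance = 1e-12)
})

test_that("with a single cell type every probe is flat across pure samples", {
  cfg <- synthConfig(nSamplesPerStratum = 3, nCelltypes = 1,
                     nMarkersPerCell = 5, nPlantedModules = 1,
                     moduleSize = 10, nNoiseProbes = 10, diseaseEffect = 0,
                     sexEffect = 0, markerClassLoading = 0,
                     moduleLatentSd = 0, noiseSd = 0, seed = 2)
  ds <- generateDataset(cfg)
  ## proportions are identically 1, so each probe's expression vector is
  ## proportional to (here: equal to) its signature level
  expect_true(all(ds$truth$proportions == 1))
  expect_equal(apply(ds$expr, 1, sd), setNames(rep(0, nrow(ds$expr)),
                                               rownames(ds$expr)))
})

test_that("the same configuration is reproduced byte-identically", {
  cfg <- synthConfig(nSamplesPerStratum = 3, nNoiseProbes = 30, seed = 77)
  a <- generateDataset(cfg)
  b <- generateDataset(cfg)
  expect_identical(a$expr, b$expr)
  expect_identical(a$pheno, b$pheno)
  expect_identical(a$truth, b$truth)
  expect_identical(generateAnnotations(a), generateAnnotations(b))
})

test_that("configuration errors are rejected", {
  expect_error(synthConfig(nCelltypes = 0), "configuration error")
  expect_error(synthConfig(noiseSd = -1), "configuration error")
  expect_error(synthConfig(proportionShift = 1.2), "configuration error")
})

test_that("annotation fixtures are consistent with the ground truth", {
  cfg <- synthConfig(nSamplesPerStratum = 3, nNoiseProbes = 200, seed = 5)
  ds <- generateDataset(cfg)
  ann <- generateAnnotations(ds)
  p2s <- ann@probe2symbol
  ## zero-dropout collection equals the truth marker sets exactly
  for (cell in names(ds$truth$markerSets)) {
    expect_setequal(ann@markerCollections$xp1[[paste0(cell, ".xp1")]],
                    unname(p2s[ds$truth$markerSets[[cell]]]))
  }
  ## dropout collection lost the declared fraction
  n1 <- lengths(ann@markerCollections$xp1)
  n2 <- lengths(ann@markerCollections$xp2)
  expect_equal(unname(n2), unname(n1 - floor(0.2 * n1)))
  ## pathway collection 1 shares exactly moduleSize symbols with module 1
  pm1 <- unname(p2s[names(ds$truth$moduleMembership)[
    ds$truth$moduleMembership == "PM01"]])
  inter <- lapply(ann@pathwayCollections$reactomeLike, intersect, y = pm1)
  expect_equal(length(inter$RCT_path01), cfg$moduleSize)
  expect_true(all(lengths(inter[names(inter) != "RCT_path01"]) == 0))
  ## basis covers exactly the marker probes
  expect_setequal(rownames(ann@basis), unlist(ds$truth$markerSets))
})

test_that("written GMT fixtures obey the format and round-trip", {
  cfg <- synthConfig(nSamplesPerStratum = 3, nNoiseProbes = 50, seed = 6)
  ds <- generateDataset(cfg)
  ann <- generateAnnotations(ds)
  dir <- withr::local_tempdir()
  writeFixtures(ds, ann, dir)
  for (f in list.files(dir, pattern = "\\.gmt$", full.names = TRUE)) {
    for (line in readLines(f))
      expect_gte(length(strsplit(line, "\t")[[1]]), 3)
    back <- readGMT(f)
    expect_true(length(back) >= 1)
  }
  ## reader agrees with an independent GMT implementation
  f <- file.path(dir, "predefined_modules.gmt")
  ours <- readGMT(f)
  theirs <- fgsea::gmtPathways(f)
  expect_identical(names(ours), names(theirs))
  expect_identical(unname(lapply(ours, sort)), unname(lapply(theirs, sort)))
})

test_that("the toy graph fixture has exactly one strong pheno-module-probe path", {
  g <- toyGraphFixture()
  q <- "(pheno)-[weight>0.6]-(wgcna)-[]-(PROBE{logfc>2})-[]-(SYMBOL)"
  res <- matchPattern(g, q)
  expect_length(res$paths, 1)
  ## correlation weights never exceed 1
  expect_length(matchPattern(g, "(pheno)-[weight>1.0]-(wgcna)-[]-(PROBE)-[]-(SYMBOL)")$paths, 0)
  ## with vacuous thresholds every 4-node path comes back
  all4 <- matchPattern(g, "(pheno)-[weight>-1]-(wgcna)-[]-(PROBE{logfc>-99})-[]-(SYMBOL)")
  expect_length(all4$paths, 9)
  expect_identical(lapply(all4$paths, unname), brutePaths(g, "(pheno)-[weight>-1]-(wgcna)-[]-(PROBE{logfc>-99})-[]-(SYMBOL)"))
})
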