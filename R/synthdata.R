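## Synthetic data with known ground truth: a cell-mixture expression model
## with planted co-expression modules, a two-factor (class x sex) phenotype
## design, and annotation fixtures derived from the same truth.

#' Synthetic-dataset configuration
#'
#' Defines the generative model for a synthetic microarray-like dataset:
#' linear-scale expression is a cell-mixture (`signature %*% t(proportions)`)
#' modulated multiplicatively by planted co-expression module factors and
#' log-normal noise. Samples form a factorial design over disease class
#' (case/control) and sex (F/M); planted module 1 is disease-linked and
#' planted module 2 (if present) sex-linked.
#'
#' @param nSamplesPerStratum samples per (class x sex) cell; default 15
#'   (60 samples total).
#' @param nCelltypes number of cell types in the mixture; default 5.
#' @param nMarkersPerCell marker probes per cell type; default 20.
#' @param nPlantedModules number of planted co-expression modules; default 4.
#' @param moduleSize probes per planted module; default 50.
#' @param nNoiseProbes unstructured background probes; default 1700 (total
#'   probe count ~2000 at defaults).
#' @param diseaseEffect log2 shift applied to the disease-linked module in
#'   cases; default 1.
#' @param sexEffect log2 shift applied to the sex-linked module in males;
#'   default 1.
#' @param proportionShift absolute increase of cell type 1's proportion in
#'   cases (other cells rescaled so rows stay on the simplex); default 0.15.
#' @param proportionJitterSd log-normal SD of per-sample cell-proportion
#'   variation; default 0.4 (blood cell fractions vary substantially between
#'   individuals, and this variation is what makes marker probes co-vary).
#' @param markerClassLoading loading of the disease latent factor on the
#'   shifted cell type's marker probes (disease-associated transcriptional
#'   activation of the expanded cell); default 0.5.
#' @param moduleLatentSd SD of the shared latent factor driving each planted
#'   module (log2 scale); default 0.5.
#' @param noiseSd residual SD on the log2 scale; default 0.5.
#' @param seed RNG seed.
#' @return a validated `SynthConfig` (list with class attribute).
#' @export
synthConfig <- function(nSamplesPerStratum = 15, nCelltypes = 5,
                        nMarkersPerCell = 20, nPlantedModules = 4,
                        moduleSize = 50, nNoiseProbes = 1700,
                        diseaseEffect = 1, sexEffect = 1,
                        proportionShift = 0.15, proportionJitterSd = 0.4,
                        markerClassLoading = 0.5, moduleLatentSd = 0.5,
                        noiseSd = 0.5, seed = 1) {
  cfg <- list(nSamplesPerStratum = nSamplesPerStratum,
              nCelltypes = nCelltypes, nMarkersPerCell = nMarkersPerCell,
              nPlantedModules = nPlantedModules, moduleSize = moduleSize,
              nNoiseProbes = nNoiseProbes, diseaseEffect = diseaseEffect,
              sexEffect = sexEffect, proportionShift = proportionShift,
              proportionJitterSd = proportionJitterSd,
              markerClassLoading = markerClassLoading,
              moduleLatentSd = moduleLatentSd, noiseSd = noiseSd, seed = seed)
  counts <- cfg[c("nSamplesPerStratum", "nCelltypes", "nMarkersPerCell",
                  "nPlantedModules", "moduleSize")]
  if (any(vapply(counts, function(x) x < 1 || x != round(x), TRUE)))
    stop("configuration error: counts must be integers >= 1")
  if (nNoiseProbes < 0 || noiseSd < 0 || moduleLatentSd < 0)
    stop("configuration error: nNoiseProbes, noiseSd, moduleLatentSd must be >= 0")
  if (proportionShift < 0 || proportionShift >= 1)
    stop("configuration error: proportionShift must be in [0, 1)")
  structure(cfg, class = "SynthConfig")
}

#' Generate a synthetic dataset with ground truth
#'
#' @param config a [synthConfig()].
#' @return list with elements `expr` (linear-scale probes x samples matrix),
#'   `pheno` (data.frame: class, sex, two numeric covariates, subject id),
#'   `se` (a `SummarizedExperiment` of the same, un-normalized) and `truth`
#'   (proportions on the simplex, cell signature, probe -> planted-module
#'   membership, effect table, per-sample latent module factors, marker
#'   probe sets). Identical configs give byte-identical outputs.
#' @export
generateDataset <- function(config, template = NULL) {
  stopifnot(inherits(config, "SynthConfig"))
  set.seed(config$seed)
  n <- config$nSamplesPerStratum
  strata <- expand.grid(sex = c("F", "M"), class = c("case", "control"),
                        stringsAsFactors = FALSE)
  pheno <- data.frame(
    class = rep(strata$class, each = n),
    sex = rep(strata$sex, each = n),
    stringsAsFactors = FALSE)
  ns <- nrow(pheno)
  sampleIds <- sprintf("S%03d", seq_len(ns))
  rownames(pheno) <- sampleIds

  cells <- sprintf("cell%02d", seq_len(config$nCelltypes))

  ## proportions: per-sample jitter around a fixed base composition; cases
  ## get cell 1 shifted up by proportionShift with the remainder rescaled
  base <- rev(seq_len(config$nCelltypes))^1.5
  base <- base / sum(base)
  prop <- vapply(seq_len(ns), function(i) {
    p <- base * exp(rnorm(config$nCelltypes, 0, config$proportionJitterSd))
    p <- p / sum(p)
    if (pheno$class[i] == "case" && config$nCelltypes > 1) {
      p1 <- min(p[1] + config$proportionShift, 0.95)
      p[-1] <- p[-1] * (1 - p1) / (1 - p[1])
      p[1] <- p1
    }
    p / sum(p)
  }, numeric(config$nCelltypes))
  prop <- matrix(prop, nrow = ns, ncol = config$nCelltypes, byrow = TRUE,
                 dimnames = list(sampleIds, cells))

  ## probes and the cell signature (linear scale); a template dataset (for
  ## multi-dataset builds on one platform) contributes its signature and
  ## marker sets unchanged
  markerIds <- sprintf("P%05d", seq_len(config$nCelltypes * config$nMarkersPerCell))
  nMod <- config$nPlantedModules * config$moduleSize
  moduleIds <- sprintf("P%05d", length(markerIds) + seq_len(nMod))
  noiseIds <- if (config$nNoiseProbes > 0)
    sprintf("P%05d", length(markerIds) + nMod + seq_len(config$nNoiseProbes))
  else character(0)
  probes <- c(markerIds, moduleIds, noiseIds)

  if (is.null(template)) {
    sig <- matrix(0, config$nCelltypes, length(probes),
                  dimnames = list(cells, probes))
    markerSets <- list()
    for (ci in seq_len(config$nCelltypes)) {
      mk <- markerIds[(ci - 1) * config$nMarkersPerCell + seq_len(config$nMarkersPerCell)]
      markerSets[[cells[ci]]] <- mk
      sig[, mk] <- matrix(runif(config$nCelltypes * length(mk), 1, 5),
                          config$nCelltypes, length(mk))
      sig[ci, mk] <- runif(length(mk), 150, 300)
    }
    ## module and noise probes are expressed uniformly across cell types, so
    ## mixture expression equals the probe's base level (rows sum to 1)
    for (p in c(moduleIds, noiseIds))
      sig[, p] <- runif(1, 30, 150)
  } else {
    sig <- template$truth$signature
    markerSets <- template$truth$markerSets
    stopifnot(identical(colnames(sig), probes))
  }

  expr <- t(sig) %*% t(prop)          # probes x samples, linear scale

  ## planted co-expression modules: shared latent factor per module, with a
  ## class (module 1) or sex (module 2) mean shift; multiplicative on the
  ## linear scale (log2-additive)
  membership <- setNames(rep("noise", length(probes)), probes)
  for (ci in seq_along(markerSets))
    membership[markerSets[[ci]]] <- paste0("marker:", cells[ci])
  latent <- matrix(0, ns, config$nPlantedModules,
                   dimnames = list(sampleIds,
                                   sprintf("PM%02d", seq_len(config$nPlantedModules))))
  effects <- data.frame(module = character(0), factor = character(0),
                        log2effect = numeric(0), stringsAsFactors = FALSE)
  for (m in seq_len(config$nPlantedModules)) {
    members <- moduleIds[(m - 1) * config$moduleSize + seq_len(config$moduleSize)]
    membership[members] <- sprintf("PM%02d", m)
    shift <- rep(0, ns)
    if (m == 1) {
      shift <- config$diseaseEffect * (pheno$class == "case")
      effects <- rbind(effects, data.frame(module = sprintf("PM%02d", m),
                                           factor = "class",
                                           log2effect = config$diseaseEffect))
    } else if (m == 2) {
      shift <- config$sexEffect * (pheno$sex == "M")
      effects <- rbind(effects, data.frame(module = sprintf("PM%02d", m),
                                           factor = "sex",
                                           log2effect = config$sexEffect))
    }
    z <- shift + rnorm(ns, 0, config$moduleLatentSd)
    latent[, m] <- z
    loading <- runif(length(members), 0.8, 1.2)
    expr[members, ] <- expr[members, ] * 2^(outer(loading, z))
  }

  ## disease-associated transcriptional activation of the expanded cell
  ## type: its marker probes load (weakly) on the disease latent factor
  if (config$nPlantedModules >= 1 && config$markerClassLoading > 0 &&
      config$nCelltypes >= 1) {
    mk <- markerSets[[1]]
    expr[mk, ] <- expr[mk, ] * 2^(config$markerClassLoading *
                                    outer(rep(1, length(mk)), latent[, 1]))
  }

  if (config$noiseSd > 0)
    expr <- expr * 2^matrix(rnorm(length(expr), 0, config$noiseSd),
                            nrow(expr), ncol(expr))

  ## numeric covariates: one tracks the disease-linked module's latent
  ## factor (R >= 0.8 by construction: noise SD = half the signal SD), one
  ## is independent
  z1 <- latent[, 1]
  covDisease <- z1 + rnorm(ns, 0, 0.5 * sd(z1))
  pheno$activity_score <- round(covDisease, 6)
  pheno$age <- round(rnorm(ns, 40, 10), 1)
  pheno$subject_id <- sprintf("SUBJ%03d", seq_len(ns))

  truth <- list(proportions = prop, signature = sig,
                moduleMembership = membership, effectTable = effects,
                latentFactors = latent, markerSets = markerSets,
                diseaseCovariate = "activity_score")
  se <- makeExperiment(expr, pheno, classVar = "class", stratVar = "sex",
                       classRef = "control", stratRef = "F",
                       idVars = "subject_id")
  list(expr = expr, pheno = pheno, se = se, truth = truth, config = config)
}

#' Generate annotation fixtures consistent with a synthetic dataset
#'
#' Emits the prior-knowledge side of a build, derived from the generator's
#' ground truth: a 1:1 probe-to-symbol map, three cell-marker collections
#' (exact truth markers; truth with a dropout fraction removed; truth with a
#' fraction swapped for decoy symbols), three pathway collections (one
#' pathway per planted module plus decoy sets, at decreasing fidelity), a
#' pre-defined module collection (half planted modules, half random sets),
#' the deconvolution signature basis restricted to marker probes, and the
#' consensus cell-name map.
#'
#' @param dataset result of [generateDataset()].
#' @param dropout fraction of markers dropped in the second collection;
#'   default 0.2.
#' @param decoy fraction of markers swapped for decoys in the third
#'   collection; default 0.2.
#' @return an [AnnotationBundle-class].
#' @export
generateAnnotations <- function(dataset, dropout = 0.2, decoy = 0.2) {
  if (is.null(dataset$truth))
    stop("dataset context missing: pass the result of generateDataset()")
  truth <- dataset$truth
  config <- dataset$config
  set.seed(config$seed + 101)
  probes <- rownames(dataset$expr)
  p2s <- setNames(sub("^P", "G", probes), probes)
  sym <- function(pr) unname(p2s[pr])
  noiseSyms <- sym(names(truth$moduleMembership)[truth$moduleMembership == "noise"])
  if (!length(noiseSyms)) noiseSyms <- sym(probes)

  cells <- names(truth$markerSets)
  markerCollections <- list(xp1 = list(), xp2 = list(), xp3 = list())
  cellNameMap <- character(0)
  for (cell in cells) {
    ms <- sym(truth$markerSets[[cell]])
    l1 <- paste0(cell, ".xp1"); l2 <- paste0(cell, ".xp2"); l3 <- paste0(cell, ".xp3")
    markerCollections$xp1[[l1]] <- ms
    nDrop <- floor(dropout * length(ms))
    markerCollections$xp2[[l2]] <- if (nDrop > 0) ms[-sample(length(ms), nDrop)] else ms
    nSwap <- floor(decoy * length(ms))
    swapped <- ms
    if (nSwap > 0)
      swapped[sample(length(ms), nSwap)] <- sample(noiseSyms, nSwap)
    markerCollections$xp3[[l3]] <- swapped
    cellNameMap[c(l1, l2, l3)] <- cell
  }
  cellNameMap[cells] <- cells               # basis columns use consensus names

  plantedSets <- lapply(seq_len(config$nPlantedModules), function(m) {
    sym(names(truth$moduleMembership)[truth$moduleMembership == sprintf("PM%02d", m)])
  })
  names(plantedSets) <- sprintf("PM%02d", seq_len(config$nPlantedModules))
  lineageSets <- lapply(truth$markerSets, sym)
  decoySet <- function(sz) sample(noiseSyms, min(sz, length(noiseSyms)))
  ## each pathway collection: one pathway per planted module (decreasing
  ## fidelity across collections), one lineage pathway per cell type, and
  ## decoy sets of random background symbols
  mkColl <- function(prefix, keepFrac, nDecoys) {
    sets <- list()
    for (m in seq_along(plantedSets)) {
      s <- plantedSets[[m]]
      keep <- max(3, round(keepFrac * length(s)))
      sets[[sprintf("%s_path%02d", prefix, m)]] <- s[seq_len(min(keep, length(s)))]
    }
    for (ci in seq_along(lineageSets))
      sets[[sprintf("%s_lineage_%s", prefix, names(lineageSets)[ci])]] <-
        lineageSets[[ci]]
    for (d in seq_len(nDecoys))
      sets[[sprintf("%s_decoy%02d", prefix, d)]] <- decoySet(config$moduleSize)
    sets
  }
  pathwayCollections <- list(
    reactomeLike = mkColl("RCT", 1.0, 5),
    curatedLike = mkColl("CUR", 0.8, 5),
    immuneLike = mkColl("IMM", 0.6, 5))

  ## pre-defined transcriptional modules: the planted programs, one lineage
  ## module per cell type (repertoire collections contain such modules),
  ## and random sets
  predef <- plantedSets
  names(predef) <- sprintf("M%d.%d", 1, seq_along(plantedSets))
  for (ci in seq_along(lineageSets))
    predef[[sprintf("M%d.%d", 2, ci)]] <- lineageSets[[ci]]
  for (d in seq_along(plantedSets)) {
    predef[[sprintf("M%d.%d", 3, d)]] <- decoySet(config$moduleSize)
  }

  markerProbes <- unlist(truth$markerSets, use.names = FALSE)
  basis <- t(truth$signature[, markerProbes, drop = FALSE])

  new("AnnotationBundle", probe2symbol = p2s,
      pathwayCollections = pathwayCollections,
      markerCollections = markerCollections,
      predefinedModules = predef, basis = basis,
      cellNameMap = cellNameMap)
}

#' Generate a replicate dataset on the same platform
#'
#' Draws a fresh cohort (new proportions, latent factors, noise and
#' phenotype) while reusing the template's probe set, cell signature and
#' marker definitions, so both datasets share one platform and one
#' annotation bundle — the situation a multi-dataset build expects.
#'
#' @param template result of [generateDataset()].
#' @param seed seed for the replicate cohort.
#' @param config optional [synthConfig()] overriding the template's
#'   (dimensions fixed by the platform must not change).
#' @return as [generateDataset()].
#' @export
generateReplicate <- function(template, seed, config = NULL) {
  cfg <- config %||% template$config
  fixed <- c("nCelltypes", "nMarkersPerCell", "nPlantedModules",
             "moduleSize", "nNoiseProbes")
  if (!identical(template$config[fixed], cfg[fixed]))
    stop("platform dimensions must match the template")
  cfg$seed <- seed
  class(cfg) <- "SynthConfig"
  generateDataset(cfg, template = template)
}

#' Write a synthetic dataset and its annotations as pipeline input files
#'
#' Emits the exact formats the build reads: expression TSV, phenotype CSV,
#' probe2symbol TSV, marker and pathway GMTs, pre-defined module GMT, basis
#' CSV, cell-name map TSV and a ready-to-run YAML configuration.
#'
#' @param datasets result of [generateDataset()], or a named list of such
#'   results (names = dataset ids / squares) sharing one platform.
#' @param annotations result of [generateAnnotations()].
#' @param dir output directory (created if needed).
#' @param minModuleSize minimum co-expression module size recorded in the
#'   emitted config; default 10 (synthetic scale).
#' @return invisibly, the path of the written YAML config.
#' @export
writeFixtures <- function(datasets, annotations, dir, minModuleSize = 10) {
  if (!is.null(datasets$truth)) datasets <- list(synth1 = datasets)
  if (is.null(names(datasets)))
    names(datasets) <- sprintf("synth%d", seq_along(datasets))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(...) file.path(dir, ...)
  dsCfg <- list()
  for (sq in names(datasets)) {
    dataset <- datasets[[sq]]
    expr <- dataset$expr
    df <- data.frame(probe_id = rownames(expr), expr, check.names = FALSE)
    utils::write.table(df, fp(sprintf("%s_expression.tsv", sq)), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    ph <- data.frame(sample_id = rownames(dataset$pheno), dataset$pheno,
                     check.names = FALSE)
    utils::write.table(ph, fp(sprintf("%s_pheno.csv", sq)), sep = ",",
                       quote = FALSE, row.names = FALSE)
    dsCfg[[length(dsCfg) + 1]] <- list(
      square = sq, edge = "1",
      expression = fp(sprintf("%s_expression.tsv", sq)),
      pheno = fp(sprintf("%s_pheno.csv", sq)),
      class_var = "class", strat_var = "sex",
      class_ref = "control", strat_ref = "F",
      id_vars = list("subject_id"))
  }
  p2s <- annotations@probe2symbol
  utils::write.table(data.frame(probe_id = names(p2s), symbol = unname(p2s)),
                     fp("probe2symbol.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  for (nm in names(annotations@markerCollections))
    writeGMT(annotations@markerCollections[[nm]],
             fp(sprintf("markers_%s.gmt", nm)))
  for (nm in names(annotations@pathwayCollections))
    writeGMT(annotations@pathwayCollections[[nm]],
             fp(sprintf("pathways_%s.gmt", nm)))
  writeGMT(annotations@predefinedModules, fp("predefined_modules.gmt"))
  basis <- annotations@basis
  utils::write.table(data.frame(probe_id = rownames(basis), basis,
                                check.names = FALSE),
                     fp("basis.csv"), sep = ",", quote = FALSE,
                     row.names = FALSE)
  cm <- annotations@cellNameMap
  utils::write.table(data.frame(collection = ifelse(grepl("\\.xp", names(cm)),
                                                    sub("^.*\\.", "", names(cm)),
                                                    "basis"),
                                label = names(cm), cell = unname(cm)),
                     fp("cellmap.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  cfg <- list(
    project = "synthetic",
    seed = datasets[[1]]$config$seed,
    thresholds = list(min_module_size = minModuleSize),
    datasets = dsCfg,
    annotations = list(
      probe2symbol = fp("probe2symbol.tsv"),
      markers = list(xp1 = fp("markers_xp1.gmt"), xp2 = fp("markers_xp2.gmt"),
                     xp3 = fp("markers_xp3.gmt")),
      pathways = list(reactomeLike = fp("pathways_reactomeLike.gmt"),
                      curatedLike = fp("pathways_curatedLike.gmt"),
                      immuneLike = fp("pathways_immuneLike.gmt")),
      predefined_modules = fp("predefined_modules.gmt"),
      basis = fp("basis.csv"), cellmap = fp("cellmap.tsv")))
  yaml::write_yaml(cfg, fp("config.yaml"))
  invisible(fp("config.yaml"))
}

#' Hand-specified toy association graph
#'
#' A small fixed graph (2 wgcna, 3 pheno, 6 PROBE and 6 SYMBOL nodes) built
#' so that exactly one path of shape
#' `(pheno)-(wgcna)-(PROBE)-(SYMBOL)` satisfies
#' `weight > 0.6` on the pheno--wgcna correlation edge together with
#' `logfc > 2` on the PROBE node. Useful for exercising pattern queries.
#'
#' @return an [AssociationGraph-class].
#' @export
toyGraphFixture <- function() {
  g <- emptyGraph()
  sq <- "toy"; ed <- "1"
  for (w in c("turquoise", "blue"))
    g <- mergeNode(g, "wgcna", w, sq, ed,
                   props = list(diffME = if (w == "turquoise") 0.4 else -0.2))
  for (p in c("bp", "crp", "temp"))
    g <- mergeNode(g, "pheno", p, sq, ed)
  logfc <- c(P1 = 2.5, P2 = 1.0, P3 = -0.5, P4 = 1.5, P5 = 0.2, P6 = -2.5)
  for (p in names(logfc))
    g <- mergeNode(g, "PROBE", p, sq, ed, props = list(logfc = unname(logfc[p])))
  for (s in paste0("S", 1:6))
    g <- mergeNode(g, "SYMBOL", s)
  wK <- function(w) nodeKey("wgcna", w, sq, ed)
  phK <- function(p) nodeKey("pheno", p, sq, ed)
  prK <- function(p) nodeKey("PROBE", p, sq, ed)
  syK <- function(s) nodeKey("SYMBOL", s)
  g <- mergeEdge(g, phK("bp"), wK("turquoise"), "correlation", 29,
                 props = list(weight = 0.7, p = 0.001, q = 0.004))
  g <- mergeEdge(g, phK("crp"), wK("turquoise"), "correlation", 29,
                 props = list(weight = 0.5, p = 0.01, q = 0.02))
  g <- mergeEdge(g, phK("temp"), wK("blue"), "correlation", 29,
                 props = list(weight = 0.65, p = 0.005, q = 0.01))
  mem <- list(turquoise = c("P1", "P2", "P3"), blue = c("P4", "P5", "P6"))
  for (w in names(mem)) for (p in mem[[w]])
    g <- mergeEdge(g, prK(p), wK(w), "mapping", 3)
  for (i in 1:6)
    g <- mergeEdge(g, prK(paste0("P", i)), syK(paste0("S", i)), "mapping", 2)
  g
}
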