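## Shared fixtures, built once per test run and cached.

.fixCache <- new.env()

fixture <- function(name, builder) {
  if (is.null(.fixCache[[name]])) .fixCache[[name]] <- builder()
  .fixCache[[name]]
}

## default-scale synthetic dataset with annotations and the co-expression
## stage computed (used by several files)
defaultRun <- function() {
  fixture("defaultRun", function() {
    cfg <- synthConfig(seed = 11)
    ds <- generateDataset(cfg)
    ann <- generateAnnotations(ds)
    se <- normalizeExpression(ds$se)
    seF <- filterProbes(se, "variance", q = 0.5)
    x <- exprs(seF)
    sp <- pickSoftPower(x)
    tom <- tomMatrix(x, sp$power)
    det <- detectModules(tom, x, minSize = 10)
    mes <- moduleEigengenes(x, det$assignment)
    list(cfg = cfg, ds = ds, ann = ann, se = se, seF = seF, x = x,
         power = sp$power, tom = tom, det = det, mes = mes)
  })
}

## small two-block co-expression dataset with a known latent structure
twoBlockExpr <- function(n = 40, perBlock = 30, rho = 0.9, seed = 42) {
  set.seed(seed)
  z1 <- rnorm(n); z2 <- rnorm(n)
  noise <- sqrt(1 / rho^2 - 1)
  x <- rbind(
    t(vapply(seq_len(perBlock), function(i) z1 + rnorm(n, 0, noise), numeric(n))),
    t(vapply(seq_len(perBlock), function(i) z2 + rnorm(n, 0, noise), numeric(n))))
  rownames(x) <- sprintf("P%03d", seq_len(2 * perBlock))
  colnames(x) <- sprintf("S%02d", seq_len(n))
  x
}

## minimal experiment wrapper for hand-built matrices
tinyExperiment <- function(x, class, sex, normalized = TRUE, ...) {
  pheno <- data.frame(class = class, sex = sex, row.names = colnames(x),
                      stringsAsFactors = FALSE)
  makeExperiment(x, pheno, "class", "sex", classRef = "control",
                 stratRef = "F", normalized = normalized, ...)
}
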