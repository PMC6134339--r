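## Readers/writers for the plain-text interchange formats: expression TSV,
## phenotype CSV, GMT collections, signature basis CSV, probe->symbol TSV.

#' Read a GMT gene-set file
#'
#' Each line is tab-separated: set name, description, then one or more gene
#' symbols.
#'
#' @param path path to a .gmt file.
#' @return named list of character vectors of symbols; the `description`
#'   attribute holds the per-set description fields.
#' @export
readGMT <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list()
  desc <- character(0)
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3)
      stop("unparseable GMT line ", i, " in ", path,
           " (need name, description and at least one gene)")
    sets[[f[1]]] <- f[-(1:2)]
    desc[f[1]] <- f[2]
  }
  attr(sets, "description") <- desc
  sets
}

#' Write a GMT gene-set file
#' @param sets named list of symbol vectors.
#' @param path output path.
#' @param description optional named character vector of descriptions.
#' @return invisibly, `path`.
#' @export
writeGMT <- function(sets, path, description = NULL) {
  lines <- vapply(names(sets), function(nm) {
    d <- if (!is.null(description) && !is.na(description[nm])) description[nm] else "na"
    paste(c(nm, d, sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read an expression matrix TSV
#'
#' First column = probe id, header row = sample ids, entries = raw (linear
#' scale) intensities.
#'
#' @param path path to the TSV.
#' @return numeric matrix, probes x samples.
#' @export
readExpression <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  probes <- as.character(dt[[1]])
  if (anyDuplicated(probes)) {
    dup <- unique(probes[duplicated(probes)])
    stop("duplicated probe id(s) in ", path, ": ",
         paste(head(dup, 5), collapse = ", "))
  }
  m <- as.matrix(dt[, -1, drop = FALSE])
  if (anyDuplicated(colnames(m)))
    stop("duplicated sample id(s) in ", path)
  rownames(m) <- probes
  storage.mode(m) <- "double"
  m
}

#' Read a phenotype table CSV
#'
#' First column = sample id; remaining columns are phenotype variables.
#'
#' @param path path to the CSV.
#' @return data.frame with rownames = sample ids.
#' @export
readPheno <- function(path) {
  df <- data.table::fread(path, sep = ",", header = TRUE, data.table = FALSE)
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids))
    stop("duplicated sample id(s) in ", path)
  df <- df[, -1, drop = FALSE]
  rownames(df) <- ids
  df
}

#' Read a signature basis CSV (rows = marker probes, columns = cell types)
#' @param path path to the CSV.
#' @return numeric matrix, probes x cell types.
#' @export
readBasis <- function(path) {
  dt <- data.table::fread(path, sep = ",", header = TRUE, data.table = FALSE)
  m <- as.matrix(dt[, -1, drop = FALSE])
  rownames(m) <- as.character(dt[[1]])
  storage.mode(m) <- "double"
  m
}

#' Read a probe-to-symbol map (two-column TSV: probe_id, symbol)
#' @param path path to the TSV.
#' @return named character vector, probe id -> symbol.
#' @export
readProbe2Symbol <- function(path) {
  df <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  map <- as.character(df[[2]])
  names(map) <- as.character(df[[1]])
  if (anyDuplicated(names(map)))
    stop("probe->symbol map has duplicate probes (mapping must be a function)")
  map
}

#' Read a cell-name map (TSV: collection, label, cell)
#'
#' Maps collection-specific cell labels to consensus CELL names.
#'
#' @param path path to the TSV.
#' @return named character vector, label -> consensus cell name.
#' @export
readCellMap <- function(path) {
  df <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  setNames(as.character(df$cell), as.character(df$label))
}
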