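#' Load a long-format phenotype table
#'
#' Expects a delimited file with header columns line, env, value. Duplicate
#' (line, env) records are rejected; missing values are allowed only when
#' \code{allowMissing = TRUE} (prediction-target masking).
#'
#' @param path CSV file path.
#' @param allowMissing permit NA trait values?
#' @return data.frame with columns line (character), env (character),
#'   value (numeric).
#' @export
loadPhenotypes <- function(path, allowMissing = FALSE) {
  raw <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("line", "env", "value")
  missingCols <- setdiff(need, names(raw))
  if (length(missingCols))
    stop("phenotype file is missing column(s): ",
         paste(missingCols, collapse = ", "))
  val <- suppressWarnings(as.numeric(raw$value))
  isBlank <- is.na(raw$value) | raw$value %in% c("", "NA")
  badRows <- which(is.na(val) & !isBlank)
  if (length(badRows))
    stop("non-numeric value in column 'value' at data row(s): ",
         paste(badRows, collapse = ", "))
  if (!allowMissing && anyNA(val))
    stop("missing trait values present; set allowMissing = TRUE for ",
         "prediction-target masking")
  key <- paste(raw$line, raw$env, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (line, env) record(s): ",
         paste(gsub("\r", "/", unique(key[duplicated(key)])), collapse = "; "))
  data.frame(line = raw$line, env = raw$env, value = val,
             stringsAsFactors = FALSE)
}

#' Load a marker genotype matrix
#'
#' Delimited file: first column line identifiers, remaining columns numeric
#' marker codes, header row of marker names. Missing genotypes are imputed
#' by column means (with a message stating the count).
#'
#' @param path CSV file path.
#' @return a \linkS4class{MarkerMatrix}.
#' @export
loadMarkers <- function(path) {
  raw <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(raw) < 2L) stop("marker file needs an ID column plus markers")
  ids <- as.character(raw[[1]])
  G <- as.matrix(raw[, -1, drop = FALSE])
  storage.mode(G) <- "double"
  rownames(G) <- ids
  markerMatrix(G, impute = TRUE)
}

#' Write a marker matrix to CSV
#' @param markers a \linkS4class{MarkerMatrix}.
#' @param path output file.
#' @export
writeMarkers <- function(markers, path) {
  G <- as.matrix(markers)
  out <- data.frame(line = rownames(G), G, check.names = FALSE,
                    stringsAsFactors = FALSE)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a kernel matrix to CSV
#'
#' Square CSV with line identifiers as both header and first column.
#'
#' @param K a \linkS4class{KernelMatrix}.
#' @param path output file.
#' @export
writeKernel <- function(K, path) {
  Km <- as.matrix(K)
  out <- data.frame(line = rownames(Km), Km, check.names = FALSE,
                    stringsAsFactors = FALSE)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a kernel matrix written by \code{\link{writeKernel}}
#' @param path CSV file path.
#' @param rho bandwidth to record on the object (NA if unknown/linear).
#' @return a \linkS4class{KernelMatrix}.
#' @export
readKernel <- function(path, rho = NA_real_) {
  raw <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  ids <- as.character(raw[[1]])
  Km <- as.matrix(raw[, -1, drop = FALSE])
  storage.mode(Km) <- "double"
  dimnames(Km) <- list(ids, ids)
  Km <- (Km + t(Km)) / 2
  new("KernelMatrix", K = Km, rho = rho)
}

#' Write an evaluation report to CSV files
#'
#' Emits \code{metrics.csv} (scope, strategy, mse, seMse, nrmse, seNrmse)
#' and \code{relative_efficiencies.csv} (comparison, scope, reMse, reNrmse).
#'
#' @param report an \linkS4class{EvaluationReport}.
#' @param dir output directory (created if absent).
#' @return paths of the files written, invisibly.
#' @export
writeReport <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  mPath <- file.path(dir, "metrics.csv")
  rPath <- file.path(dir, "relative_efficiencies.csv")
  write.csv(metricsTable(report), mPath, row.names = FALSE)
  write.csv(relativeEfficiencies(report), rPath, row.names = FALSE)
  invisible(c(mPath, rPath))
}

#' Write a reproducibility manifest
#'
#' Records every seed, the grid, the BO budget and the chain settings of an
#' experiment, plus the package version, as JSON.
#'
#' @param path output JSON file.
#' @param foldSeed fold-plan seed.
#' @param spec a \linkS4class{ModelSpec}.
#' @param grid bandwidth grid used.
#' @param boBudget BO evaluation budget.
#' @param extra optional named list of further entries.
#' @return the path, invisibly.
#' @export
writeManifest <- function(path, foldSeed, spec, grid = makeGrid(),
                          boBudget = 22, extra = list()) {
  manifest <- c(list(
    package = "KernelGBLUP",
    version = as.character(packageVersion("KernelGBLUP")),
    foldSeed = foldSeed,
    chainSeed = spec@seed,
    nIter = spec@nIter, burnIn = spec@burnIn, thin = spec@thin,
    priorDf = spec@priorDf, priorR2 = spec@priorR2,
    grid = grid, boBudget = boBudget), extra)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
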