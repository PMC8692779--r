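#' Read a log2 expression matrix from TSV
#'
#' Expects a header row of sample identifiers, then one row per gene with
#' the gene identifier in the first column and finite numeric values after.
#' Duplicate gene identifiers, ragged rows and non-numeric cells are
#' rejected with the offending line (and column) reported.
#'
#' @param path TSV file path.
#' @return Numeric matrix, genes x samples.
#' @export
readExpression <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2L) stop("readExpression: need a header and >= 1 gene row")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1L]]
  nSamples <- length(header) - 1L
  if (nSamples < 1L) stop("readExpression: header has no sample columns")
  samples <- header[-1L]
  nf <- lengths(fields[-1L])
  bad <- which(nf != nSamples + 1L)
  if (length(bad)) {
    stop("readExpression: line ", bad[1L] + 1L, " has ", nf[bad[1L]],
         " fields, expected ", nSamples + 1L)
  }
  genes <- vapply(fields[-1L], `[[`, "", 1L)
  dup <- genes[duplicated(genes)]
  if (length(dup)) {
    stop("readExpression: duplicate gene id '", dup[1L], "'")
  }
  vals <- suppressWarnings(
    vapply(fields[-1L], function(f) as.numeric(f[-1L]), numeric(nSamples)))
  mat <- t(matrix(vals, nrow = nSamples,
                  dimnames = list(samples, genes)))
  if (anyNA(mat)) {
    idx <- which(is.na(mat), arr.ind = TRUE)[1L, ]
    stop("readExpression: non-numeric or missing value at gene '",
         rownames(mat)[idx[1L]], "', sample '", colnames(mat)[idx[2L]],
         "' (line ", idx[1L] + 1L, ")")
  }
  mat
}

#' Write a log2 expression matrix as TSV
#'
#' @param expr Numeric matrix, genes x samples, with dimnames.
#' @param path Output path.
#' @export
writeExpression <- function(expr, path) {
  expr <- as.matrix(expr)
  df <- data.frame(gene = rownames(expr), expr, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene signature sets from a GMT file
#'
#' Standard GMT: one set per line, tab-separated set name, description, then
#' gene identifiers. Empty sets, duplicate set names and malformed lines are
#' rejected with the line number.
#'
#' @param path GMT file path.
#' @return Named list of character gene vectors.
#' @export
readGMT <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("readGMT: empty file")
  sets <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L) {
      stop("readGMT: line ", i, " malformed (need name, description, >= 1 gene)")
    }
    nm <- f[[1L]]
    genes <- f[-(1:2)]
    genes <- genes[nzchar(genes)]
    if (length(genes) == 0L) stop("readGMT: line ", i, " has an empty gene set")
    if (nm %in% names(sets)) stop("readGMT: duplicate set name '", nm, "' at line ", i)
    sets[[nm]] <- genes
  }
  sets
}

#' Write gene signature sets as GMT
#'
#' @param sigs Named list of gene identifier vectors.
#' @param path Output path.
#' @param descriptions Optional per-set description column (defaults to the
#'   set name).
#' @export
writeGMT <- function(sigs, path, descriptions = names(sigs)) {
  if (is.null(names(sigs))) stop("writeGMT: sets must be named")
  lines <- vapply(seq_along(sigs), function(i) {
    paste(c(names(sigs)[i], descriptions[i], sigs[[i]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a clinical annotation table from TSV
#'
#' @param path TSV path; must contain a \code{sample_id} column. Columns
#'   listed in \code{required} must be present.
#' @param required Character vector of required column names.
#' @return A data.frame keyed by \code{sample_id}.
#' @export
readClinical <- function(path, required = character(0)) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  need <- unique(c("sample_id", required))
  missing <- setdiff(need, colnames(df))
  if (length(missing)) {
    stop("readClinical: missing column(s): ", paste(missing, collapse = ", "))
  }
  if (anyDuplicated(df$sample_id)) stop("readClinical: duplicate sample_id")
  df
}

#' Read a single-cell MTX bundle into a SingleCellExperiment
#'
#' MatrixMarket coordinate counts (1-based indices per the MatrixMarket
#' standard; genes as rows), a features file (first column gene ids), a
#' barcodes file (one barcode per line) and a cell metadata TSV with columns
#' barcode, tumor_id, cell_type and optionally subtype. Metadata rows may be
#' in any order; every barcode must be covered.
#'
#' @param matrixPath,featuresPath,barcodesPath,metaPath File paths.
#' @return A \code{SingleCellExperiment} with a sparse \code{counts} assay,
#'   cell metadata in \code{colData} and a mitochondrial flag ("MT-" prefix)
#'   in \code{rowData}.
#' @export
readMtxBundle <- function(matrixPath, featuresPath, barcodesPath, metaPath) {
  m <- Matrix::readMM(matrixPath)
  features <- utils::read.delim(featuresPath, header = FALSE,
                                stringsAsFactors = FALSE)[[1L]]
  barcodes <- readLines(barcodesPath)
  barcodes <- barcodes[nzchar(barcodes)]
  if (nrow(m) != length(features)) {
    stop("readMtxBundle: matrix has ", nrow(m), " rows but ",
         length(features), " features")
  }
  if (ncol(m) != length(barcodes)) {
    stop("readMtxBundle: matrix has ", ncol(m), " columns but ",
         length(barcodes), " barcodes")
  }
  meta <- utils::read.delim(metaPath, stringsAsFactors = FALSE)
  need <- c("barcode", "tumor_id", "cell_type")
  missing <- setdiff(need, colnames(meta))
  if (length(missing)) {
    stop("readMtxBundle: metadata missing column(s): ",
         paste(missing, collapse = ", "))
  }
  idx <- match(barcodes, meta$barcode)
  if (anyNA(idx)) {
    stop("readMtxBundle: barcode '", barcodes[which(is.na(idx))[1L]],
         "' absent from metadata")
  }
  meta <- meta[idx, setdiff(colnames(meta), "barcode"), drop = FALSE]
  rownames(meta) <- barcodes
  m <- methods::as(m, "CsparseMatrix")
  dimnames(m) <- list(features, barcodes)
  sce <- SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = m), colData = S4Vectors::DataFrame(meta))
  SummarizedExperiment::rowData(sce)$mito <- grepl("^MT-", rownames(sce))
  sce
}

#' Write a SingleCellExperiment as an MTX bundle
#'
#' @param sce A \code{SingleCellExperiment} with a counts assay and colData
#'   columns tumor_id, cell_type (and optionally subtype).
#' @param dir Output directory (created if needed). Writes matrix.mtx,
#'   features.tsv, barcodes.tsv, cell_metadata.tsv.
#' @export
writeMtxBundle <- function(sce, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  counts <- SummarizedExperiment::assay(sce, "counts")
  Matrix::writeMM(counts, file.path(dir, "matrix.mtx"))
  writeLines(rownames(sce), file.path(dir, "features.tsv"))
  writeLines(colnames(sce), file.path(dir, "barcodes.tsv"))
  meta <- as.data.frame(SummarizedExperiment::colData(sce))
  meta <- cbind(data.frame(barcode = colnames(sce)),
                meta[, setdiff(colnames(meta), "mito"), drop = FALSE])
  utils::write.table(meta, file.path(dir, "cell_metadata.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Run configuration with validated thresholds
#'
#' Bundles the pipeline's tunable parameters: the antagonist Z cut, the two
#' FDR thresholds (per-gene survival screen; single-cell/activation DE), the
#' quantile bin counts, the subclass coding and the survival horizon.
#' Round-trips losslessly through JSON.
#'
#' @param seed Integer seed.
#' @param zCut Antagonist threshold on the interaction Z (default -2).
#' @param fdrSurvival BH threshold of the survival screen (default 0.1).
#' @param fdrDE BH threshold of differential expression (default 0.01).
#' @param tertileK,quartileK Quantile bin counts (3 and 4).
#' @param coding Subclass coding, "ordinal" or "dummy".
#' @param horizonYears Survival horizon (default 10).
#' @return A validated list of class \code{trem_config}.
#' @export
runConfig <- function(seed = 1L, zCut = -2.0, fdrSurvival = 0.1,
                      fdrDE = 0.01, tertileK = 3L, quartileK = 4L,
                      coding = c("ordinal", "dummy"), horizonYears = 10) {
  coding <- match.arg(coding)
  stopifnot(fdrSurvival > 0, fdrSurvival < 1, fdrDE > 0, fdrDE < 1,
            tertileK >= 2, quartileK >= 2, horizonYears > 0)
  zCut <- as.numeric(zCut)
  fdrSurvival <- as.numeric(fdrSurvival)
  fdrDE <- as.numeric(fdrDE)
  horizonYears <- as.numeric(horizonYears)
  structure(list(seed = as.integer(seed), zCut = zCut,
                 fdrSurvival = fdrSurvival, fdrDE = fdrDE,
                 tertileK = as.integer(tertileK),
                 quartileK = as.integer(quartileK), coding = coding,
                 horizonYears = horizonYears),
            class = "trem_config")
}

#' @rdname runConfig
#' @param config A \code{trem_config}.
#' @param path JSON path.
#' @export
writeConfig <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname runConfig
#' @export
readConfig <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(runConfig, raw)
}
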