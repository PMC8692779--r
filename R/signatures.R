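#' @describeIn scoreSignatures Score a log2 expression matrix (genes x
#'   samples). Signature genes absent from the matrix are dropped with a
#'   warning; a signature with no present genes is an error. Each score is
#'   the log-scale geometric mean over the signature's present genes.
#' @export
setMethod("scoreSignatures", signature(expr = "matrix", sigs = "list"),
  function(expr, sigs, ...) {
    if (is.null(rownames(expr))) stop("expression matrix must have gene rownames")
    if (is.null(names(sigs)) || anyDuplicated(names(sigs))) {
      stop("signatures must be uniquely named")
    }
    if (any(vapply(sigs, length, 1L) == 0L)) stop("empty signature gene set")
    scores <- vapply(names(sigs), function(nm) {
      genes <- unique(sigs[[nm]])
      present <- intersect(genes, rownames(expr))
      if (length(present) == 0L) {
        stop("signature '", nm, "' has no genes present in the matrix")
      }
      if (length(present) < length(genes)) {
        warning("signature '", nm, "': dropped ",
                length(genes) - length(present), " absent gene(s)")
      }
      colMeans(expr[present, , drop = FALSE])
    }, numeric(ncol(expr)))
    rownames(scores) <- colnames(expr)
    scores
  })

#' @describeIn scoreSignatures Score the \code{exprs} (or first) assay of a
#'   SummarizedExperiment.
#' @importFrom SummarizedExperiment assay assayNames
#' @export
setMethod("scoreSignatures",
  signature(expr = "SummarizedExperiment", sigs = "list"),
  function(expr, sigs, ...) {
    nm <- if ("exprs" %in% assayNames(expr)) "exprs" else 1L
    scoreSignatures(as.matrix(assay(expr, nm)), sigs, ...)
  })

#' Assign FID/WID/PID immune subclasses by the population tertile rule
#'
#' For each of the three signatures, samples are ranked into cohort-relative
#' tertiles of their score. A tumor in the upper tertile of all three
#' signatures simultaneously is FID; a tumor in the lowest tertile of any one
#' signature is PID; every other combination of intermediate and upper
#' tertiles is WID.
#'
#' @param scores Numeric matrix (samples x 3) as returned by
#'   \code{\link{scoreSignatures}}, columns ordered T/NK, B/P, M/D.
#' @return An \code{\link{ImmuneAssignment-class}} object.
#' @export
assignSubclasses <- function(scores) {
  scores <- as.matrix(scores)
  if (ncol(scores) != 3L) stop("assignSubclasses: need exactly 3 score columns")
  if (nrow(scores) < 3L) stop("assignSubclasses: need at least 3 samples")
  if (any(!is.finite(scores))) stop("assignSubclasses: non-finite scores")
  ids <- rownames(scores)
  if (is.null(ids)) ids <- paste0("sample_", seq_len(nrow(scores)))
  tert <- apply(scores, 2L, quantileBin, k = 3L)
  storage.mode(tert) <- "integer"
  lab <- ifelse(apply(tert == 3L, 1L, all), "FID",
         ifelse(apply(tert == 1L, 1L, any), "PID", "WID"))
  colnames(tert) <- colnames(scores)
  new("ImmuneAssignment",
      sampleId = ids,
      scores = scores,
      tertiles = tert,
      subclass = factor(lab, levels = c("FID", "WID", "PID")))
}

#' @rdname ImmuneAssignment-class
#' @export
setMethod("subclass", "ImmuneAssignment", function(x) {
  stats::setNames(x@subclass, x@sampleId)
})

#' @rdname ImmuneAssignment-class
#' @export
setMethod("signatureScores", "ImmuneAssignment", function(x) x@scores)

#' @rdname ImmuneAssignment-class
#' @export
setMethod("tertiles", "ImmuneAssignment", function(x) x@tertiles)

#' @rdname ImmuneAssignment-class
#' @export
setMethod("sampleIds", "ImmuneAssignment", function(x) x@sampleId)

#' @rdname ImmuneAssignment-class
#' @param object An \code{ImmuneAssignment}.
#' @export
setMethod("show", "ImmuneAssignment", function(object) {
  tab <- table(object@subclass)
  cat("ImmuneAssignment with", length(object@sampleId), "samples\n")
  cat(sprintf("  FID: %d  WID: %d  PID: %d\n", tab["FID"], tab["WID"], tab["PID"]))
})

#' Ordinal coding of immune subclasses
#'
#' PID = 0, WID = 1, FID = 2: the immunologic continuum from cold to
#' inflamed, used as the single ordinal factor entering the interaction
#' product term.
#'
#' @param subclass Factor or character vector of FID/WID/PID labels.
#' @return Integer vector in 0..2.
#' @export
subclassOrdinal <- function(subclass) {
  subclass <- as.character(subclass)
  if (!all(subclass %in% c("FID", "WID", "PID"))) {
    stop("subclassOrdinal: labels must be FID, WID or PID")
  }
  unname(c(PID = 0L, WID = 1L, FID = 2L)[subclass])
}

#' Write immune assignments as TSV
#'
#' @param x An \code{ImmuneAssignment}.
#' @param path Output file path.
#' @return Invisibly, the written data.frame.
#' @export
writeAssignments <- function(x, path) {
  stopifnot(is(x, "ImmuneAssignment"))
  df <- data.frame(
    sample_id = x@sampleId,
    score_tnk = x@scores[, 1L], score_bp = x@scores[, 2L],
    score_md = x@scores[, 3L],
    tert_tnk = x@tertiles[, 1L], tert_bp = x@tertiles[, 2L],
    tert_md = x@tertiles[, 3L],
    subclass = as.character(x@subclass),
    row.names = NULL
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
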