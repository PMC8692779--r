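#' @rdname ImmuneAssignment-class
#' @param x An object.
#' @export
setGeneric("subclass", function(x) standardGeneric("subclass"))

#' @rdname ImmuneAssignment-class
#' @export
setGeneric("signatureScores", function(x) standardGeneric("signatureScores"))

#' @rdname ImmuneAssignment-class
#' @export
setGeneric("tertiles", function(x) standardGeneric("tertiles"))

#' @rdname ImmuneAssignment-class
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname InteractionScreen-class
#' @param x An object.
#' @export
setGeneric("screenResults", function(x) standardGeneric("screenResults"))

#' @rdname InteractionScreen-class
#' @export
setGeneric("flaggedGenes", function(x) standardGeneric("flaggedGenes"))

#' @rdname TargetPanel-class
#' @param x An object.
#' @export
setGeneric("panelGenes", function(x) standardGeneric("panelGenes"))

#' @rdname TargetPanel-class
#' @export
setGeneric("panelEvidence", function(x) standardGeneric("panelEvidence"))

#' Score immune gene signatures
#'
#' @param expr An expression container (matrix or SummarizedExperiment).
#' @param sigs A named list of signature gene identifier vectors.
#' @param ... Further arguments passed to methods.
#' @export
setGeneric("scoreSignatures", function(expr, sigs, ...)
  standardGeneric("scoreSignatures"))
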