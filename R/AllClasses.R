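#' @import methods
#' @importFrom S4Vectors DataFrame
NULL

#' ImmuneAssignment: per-sample immune signature scores and subclass labels
#'
#' Holds the three effector immune signature scores (T/NK cytolytic, B/P
#' humoral, M/D antigen-presenting) on the log2 scale, their cohort-relative
#' tertile ranks, and the resulting immune subclass per sample. Subclasses:
#' FID (favorable immune disposition, all three signatures in the upper
#' tertile), PID (poor, any signature in the lowest tertile) and WID (weak,
#' everything else). FID/WID/PID partition the cohort.
#'
#' @slot sampleId character vector of sample identifiers.
#' @slot scores numeric matrix (samples x 3) of signature scores, columns
#'   \code{tnk}, \code{bp}, \code{md}.
#' @slot tertiles integer matrix (samples x 3) of tertile indices in 1..3.
#' @slot subclass factor with levels FID, WID, PID.
#' @export
setClass("ImmuneAssignment",
  representation(
    sampleId = "character",
    scores = "matrix",
    tertiles = "matrix",
    subclass = "factor"
  )
)

setValidity("ImmuneAssignment", function(object) {
  n <- length(object@sampleId)
  msgs <- character(0)
  if (nrow(object@scores) != n || nrow(object@tertiles) != n ||
      length(object@subclass) != n) {
    msgs <- c(msgs, "sampleId, scores, tertiles and subclass lengths differ")
  }
  if (ncol(object@scores) != 3L || ncol(object@tertiles) != 3L) {
    msgs <- c(msgs, "scores and tertiles must have 3 columns")
  }
  if (!identical(levels(object@subclass), c("FID", "WID", "PID"))) {
    msgs <- c(msgs, "subclass levels must be FID, WID, PID")
  }
  if (length(msgs) == 0 && n > 0) {
    tert <- object@tertiles
    if (any(!tert %in% 1:3)) {
      msgs <- c(msgs, "tertiles must lie in 1..3")
    } else {
      expected <- ifelse(apply(tert == 3L, 1L, all), "FID",
                  ifelse(apply(tert == 1L, 1L, any), "PID", "WID"))
      if (!all(as.character(object@subclass) == expected)) {
        msgs <- c(msgs, "subclass labels inconsistent with the tertile rule")
      }
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' InteractionScreen: ranked results of the gene-by-subclass screen
#'
#' One row per screened gene: interaction log-odds coefficient, standard
#' error, signed Wald Z, two-sided p, convergence and detection-filter flags,
#' ascending-Z rank among converged genes, and the antagonist flag
#' (Z <= zCut, default -2).
#'
#' @slot results a \code{DataFrame} with columns gene, passedFilter, coef,
#'   se, z, p, converged, rank, flagged.
#' @slot zCut numeric antagonist threshold on Z.
#' @slot coding character, "ordinal" or "dummy" subclass coding.
#' @slot nTotal integer, genes in the input matrix.
#' @slot nFiltered integer, genes passing the detection filter.
#' @export
setClass("InteractionScreen",
  representation(
    results = "DataFrame",
    zCut = "numeric",
    coding = "character",
    nTotal = "integer",
    nFiltered = "integer"
  )
)

setValidity("InteractionScreen", function(object) {
  need <- c("gene", "passedFilter", "coef", "se", "z", "p", "converged",
            "rank", "flagged")
  if (!all(need %in% colnames(object@results))) {
    return(paste("results must contain columns:", paste(need, collapse = ", ")))
  }
  res <- object@results
  ranked <- !is.na(res$rank)
  if (any(ranked) && !setequal(res$rank[ranked], seq_len(sum(ranked)))) {
    return("rank must be a permutation of 1..n over ranked genes")
  }
  fitted <- !is.na(res$z)
  if (any(res$flagged[fitted] != (res$z[fitted] <= object@zCut))) {
    return("flagged must equal z <= zCut")
  }
  TRUE
})

#' TargetPanel: cross-dataset target gene panel with evidence flags
#'
#' Genes significantly up-regulated in focal-gene-positive myeloid cells in
#' both tumor single-cell datasets and significantly induced in the
#' activation dataset.
#'
#' @slot genes character vector of panel member genes.
#' @slot evidence \code{DataFrame}, one row per shared gene, with logical
#'   columns \code{up_tumorA}, \code{up_tumorB}, \code{up_activation} and
#'   \code{member}.
#' @slot direction character, direction of regulation defining membership.
#' @export
setClass("TargetPanel",
  representation(
    genes = "character",
    evidence = "DataFrame",
    direction = "character"
  )
)

setValidity("TargetPanel", function(object) {
  need <- c("gene", "up_tumorA", "up_tumorB", "up_activation", "member")
  if (!all(need %in% colnames(object@evidence))) {
    return(paste("evidence must contain columns:", paste(need, collapse = ", ")))
  }
  ev <- object@evidence
  member <- ev$up_tumorA & ev$up_tumorB & ev$up_activation
  if (!all(ev$member == member)) {
    return("member must be the conjunction of the three evidence flags")
  }
  if (!setequal(object@genes, ev$gene[ev$member])) {
    return("genes must equal the evidence rows flagged as members")
  }
  TRUE
})
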