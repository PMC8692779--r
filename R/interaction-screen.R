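#' Detection filter on mean expression
#'
#' Keeps a gene iff its mean expression across samples is strictly greater
#' than the median of all gene means, restricting a screen to well-detected
#' genes (ties at the median are dropped).
#'
#' @param expr Log2 expression matrix, genes x samples.
#' @return Named logical vector, one entry per gene.
#' @export
detectionFilter <- function(expr) {
  expr <- as.matrix(expr)
  if (nrow(expr) < 2L) stop("detectionFilter: need at least 2 genes")
  m <- rowMeans(expr)
  m > stats::median(m)
}

#' Dichotomize one gene at the cohort median
#'
#' High (1) iff strictly above the cohort median of that gene's expression.
#'
#' @param exprRow Numeric vector of one gene's expression across samples.
#' @return Integer 0/1 vector.
#' @export
dichotomizeGene <- function(exprRow) {
  if (length(exprRow) < 2L) stop("dichotomizeGene: need at least 2 samples")
  if (any(!is.finite(exprRow))) stop("dichotomizeGene: non-finite values")
  as.integer(exprRow > stats::median(exprRow))
}

#' Fit the gene-by-subclass interaction logistic model
#'
#' Logistic regression of binary chemotherapy response on immune subclass,
#' patient age, the dichotomized gene, and the gene x subclass product term.
#' With the default ordinal coding (PID = 0, WID = 1, FID = 2) there is a
#' single product term whose coefficient measures how strongly high gene
#' expression antagonizes (negative sign) or reinforces the subclass effect
#' on response. The dummy coding fits separate WID and FID contrasts and
#' reports the FID x gene term.
#'
#' Fitting is IRLS (epsilon 1e-8, at most 100 iterations). Fits that do not
#' converge or that show quasi-complete separation are returned with
#' \code{converged = FALSE} and no z/p.
#'
#' @param response Binary 0/1 vector (1 = favorable response).
#' @param subclass FID/WID/PID labels, one per sample.
#' @param age Numeric ages, or NULL to omit the age covariate.
#' @param geneHigh Binary 0/1 vector from \code{\link{dichotomizeGene}}.
#' @param coding "ordinal" (default) or "dummy".
#' @return A list with \code{coef}, \code{se}, \code{z}, \code{p},
#'   \code{chi2}, \code{converged} (interaction term), plus
#'   \code{coefficients}, the full named coefficient vector.
#' @export
fitInteractionModel <- function(response, subclass, age, geneHigh,
                                coding = c("ordinal", "dummy")) {
  coding <- match.arg(coding)
  n <- length(response)
  if (length(subclass) != n || length(geneHigh) != n ||
      (!is.null(age) && length(age) != n)) {
    stop("fitInteractionModel: input lengths differ")
  }
  if (!all(response %in% c(0, 1))) stop("fitInteractionModel: response must be 0/1")
  if (length(unique(response)) < 2L) {
    stop("fitInteractionModel: both response classes must be present")
  }
  ord <- subclassOrdinal(subclass)
  g <- as.numeric(geneHigh)
  if (coding == "ordinal") {
    X <- cbind(`(Intercept)` = 1, subclass_ord = ord, gene_high = g,
               `gene_high:subclass_ord` = g * ord)
    term <- "gene_high:subclass_ord"
  } else {
    wid <- as.numeric(subclass == "WID")
    fid <- as.numeric(subclass == "FID")
    X <- cbind(`(Intercept)` = 1, subclassWID = wid, subclassFID = fid,
               gene_high = g,
               `gene_high:subclassWID` = g * wid,
               `gene_high:subclassFID` = g * fid)
    term <- "gene_high:subclassFID"
  }
  if (!is.null(age)) {
    X <- cbind(X[, 1L, drop = FALSE], age = as.numeric(age),
               X[, -1L, drop = FALSE])
  }
  fit <- suppressWarnings(stats::glm.fit(
    X, response, family = stats::binomial(),
    control = stats::glm.control(epsilon = 1e-8, maxit = 100)
  ))
  p <- ncol(X)
  coefs <- fit$coefficients
  # quasi-complete separation: fitted probabilities pinned at 0/1
  separated <- any(fit$fitted.values < 1e-8 | fit$fitted.values > 1 - 1e-8)
  ok <- fit$converged && !separated && !any(is.na(coefs)) && fit$rank == p
  out <- list(coefficients = coefs, converged = ok,
              coef = NA_real_, se = NA_real_, z = NA_real_,
              chi2 = NA_real_, p = NA_real_)
  if (ok) {
    p1 <- seq_len(fit$rank)
    covmat <- chol2inv(fit$qr$qr[p1, p1, drop = FALSE])
    se <- sqrt(diag(covmat))
    names(se) <- colnames(X)[fit$qr$pivot[p1]]
    w <- waldZP(unname(coefs[term]), unname(se[term]))
    out$coef <- unname(coefs[term])
    out$se <- unname(se[term])
    out$z <- w$z
    out$chi2 <- w$chi2
    out$p <- w$p
  }
  out
}

#' Genome-wide gene-by-subclass interaction screen
#'
#' Applies the detection filter, dichotomizes each retained gene at its
#' cohort median, fits the interaction logistic model per gene, and ranks
#' converged genes by ascending signed Wald Z (most antagonistic first).
#' Genes with Z at or below \code{zCut} are flagged as candidate antagonists
#' of immune-mediated chemotherapy response. Z ties are broken by gene
#' identifier.
#'
#' @param expr Log2 expression matrix, genes x samples (named dimensions).
#' @param response Binary response vector aligned to columns of \code{expr}.
#' @param assignment An \code{\link{ImmuneAssignment-class}} aligned to the
#'   same samples, or a FID/WID/PID label vector.
#' @param age Numeric age vector, or NULL.
#' @param coding Subclass coding, see \code{\link{fitInteractionModel}}.
#' @param zCut Antagonist threshold on Z (default -2, inclusive).
#' @return An \code{\link{InteractionScreen-class}} object.
#' @importFrom S4Vectors DataFrame
#' @export
runScreen <- function(expr, response, assignment, age = NULL,
                      coding = c("ordinal", "dummy"), zCut = -2.0) {
  coding <- match.arg(coding)
  expr <- as.matrix(expr)
  if (is.null(rownames(expr))) stop("runScreen: expression matrix needs gene rownames")
  labels <- if (is(assignment, "ImmuneAssignment")) {
    as.character(subclass(assignment))
  } else as.character(assignment)
  if (length(labels) != ncol(expr) || length(response) != ncol(expr)) {
    stop("runScreen: samples not aligned across inputs")
  }
  keep <- detectionFilter(expr)
  if (!any(keep)) stop("runScreen: no gene passes the detection filter")
  genes <- rownames(expr)
  fits <- lapply(which(keep), function(i) {
    gh <- dichotomizeGene(expr[i, ])
    if (length(unique(gh)) < 2L) {
      return(list(coef = NA_real_, se = NA_real_, z = NA_real_,
                  p = NA_real_, converged = FALSE))
    }
    fitInteractionModel(response, labels, age, gh, coding = coding)
  })
  res <- DataFrame(
    gene = genes,
    passedFilter = unname(keep),
    coef = NA_real_, se = NA_real_, z = NA_real_, p = NA_real_,
    converged = FALSE, rank = NA_integer_, flagged = FALSE
  )
  idx <- which(keep)
  res$coef[idx] <- vapply(fits, `[[`, 1.0, "coef")
  res$se[idx] <- vapply(fits, `[[`, 1.0, "se")
  res$z[idx] <- vapply(fits, `[[`, 1.0, "z")
  res$p[idx] <- vapply(fits, `[[`, 1.0, "p")
  res$converged[idx] <- vapply(fits, `[[`, TRUE, "converged")
  ranked <- which(res$converged)
  ord <- ranked[order(res$z[ranked], res$gene[ranked])]
  res$rank[ord] <- seq_along(ord)
  res$flagged <- !is.na(res$z) & res$converged & res$z <= zCut
  out <- res[order(is.na(res$rank), res$rank), ]
  new("InteractionScreen", results = out, zCut = zCut, coding = coding,
      nTotal = nrow(expr), nFiltered = sum(keep))
}

#' @rdname InteractionScreen-class
#' @export
setMethod("screenResults", "InteractionScreen", function(x) x@results)

#' @rdname InteractionScreen-class
#' @export
setMethod("flaggedGenes", "InteractionScreen", function(x) {
  res <- x@results
  res$gene[res$flagged][order(res$rank[res$flagged])]
})

#' @rdname InteractionScreen-class
#' @param object An \code{InteractionScreen}.
#' @export
setMethod("show", "InteractionScreen", function(object) {
  res <- object@results
  cat("InteractionScreen (", object@coding, " subclass coding)\n", sep = "")
  cat(sprintf("  %d genes; %d passed detection filter; %d converged; %d flagged (Z <= %g)\n",
              object@nTotal, object@nFiltered, sum(res$converged),
              sum(res$flagged), object@zCut))
})

#' Response-rate contrasts within and across subclasses
#'
#' For each immune subclass x gene level (low/high) stratum, the fraction of
#' favorable responders; within each subclass, a Yates-corrected chi-square
#' test of the low-vs-high 2x2 table and the fold change of the favorable
#' response fraction (low over high). Empty strata are omitted with a
#' warning.
#'
#' @param response Binary 0/1 response vector.
#' @param subclass FID/WID/PID labels.
#' @param geneHigh Binary 0/1 gene level vector.
#' @return A list with \code{rates} (data.frame subclass, gene_level, n,
#'   responders, fraction) and \code{contrasts} (data.frame subclass, fold,
#'   stat, p).
#' @export
responseRateContrast <- function(response, subclass, geneHigh) {
  n <- length(response)
  if (length(subclass) != n || length(geneHigh) != n) {
    stop("responseRateContrast: input lengths differ")
  }
  subclass <- factor(as.character(subclass), levels = c("FID", "WID", "PID"))
  lev <- factor(ifelse(geneHigh > 0, "high", "low"), levels = c("low", "high"))
  rates <- do.call(rbind, lapply(levels(subclass), function(sc) {
    do.call(rbind, lapply(levels(lev), function(gl) {
      sel <- subclass == sc & lev == gl
      if (!any(sel)) return(NULL)
      data.frame(subclass = sc, gene_level = gl, n = sum(sel),
                 responders = sum(response[sel]),
                 fraction = mean(response[sel]))
    }))
  }))
  contrasts <- do.call(rbind, lapply(levels(subclass), function(sc) {
    lo <- subclass == sc & lev == "low"
    hi <- subclass == sc & lev == "high"
    if (!any(lo) || !any(hi)) {
      warning("responseRateContrast: empty stratum in subclass ", sc,
              "; contrast omitted")
      return(NULL)
    }
    tab <- rbind(low = c(sum(response[lo] == 1), sum(response[lo] == 0)),
                 high = c(sum(response[hi] == 1), sum(response[hi] == 0)))
    colnames(tab) <- c("favorable", "unfavorable")
    test <- tryCatch(chi2Yates(tab), error = function(e) list(stat = NA, p = NA))
    data.frame(subclass = sc, fold = mean(response[lo]) / mean(response[hi]),
               stat = test$stat, p = test$p)
  }))
  list(rates = rates, contrasts = contrasts)
}
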