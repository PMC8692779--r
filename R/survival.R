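#' Prepare the distant-recurrence survival endpoint
#'
#' Applies the 10-year horizon to raw follow-up: observations beyond the
#' horizon are administratively censored at the horizon; an event at exactly
#' the horizon is retained as an event ("within 10 years" read inclusively).
#'
#' @param time Positive follow-up times in years.
#' @param event Binary event indicator (1 = distant recurrence).
#' @param horizon Horizon in years (default 10).
#' @return A data.frame with columns \code{time} and \code{event}.
#' @export
prepareEndpoint <- function(time, event, horizon = 10) {
  if (length(time) != length(event)) stop("prepareEndpoint: length mismatch")
  if (any(!is.finite(time)) || any(time <= 0)) {
    stop("prepareEndpoint: times must be positive and finite")
  }
  if (!all(event %in% c(0, 1))) stop("prepareEndpoint: event must be 0/1")
  over <- time > horizon
  data.frame(time = pmin(time, horizon),
             event = as.integer(event == 1 & !over))
}

#' Quartile stratification of one gene's expression
#'
#' @param exprRow Numeric expression values across samples (n >= 4).
#' @return Integer quartile index 1..4 per sample (Q1 = lowest expression).
#' @export
quartileStratify <- function(exprRow) {
  if (length(exprRow) < 4L) stop("quartileStratify: need at least 4 samples")
  quantileBin(exprRow, k = 4L)
}

#' Kaplan-Meier curves and k-group log-rank test
#'
#' Product-limit survival estimates per group and the k-group log-rank
#' statistic (chi-square with k-1 df).
#'
#' @param time,event Survival times and 0/1 event indicators.
#' @param group Group labels (>= 2 non-empty groups).
#' @return A list with \code{curves} (data.frame: group, time, n_risk,
#'   n_event, survival), \code{chi2}, \code{df}, \code{p}.
#' @importFrom survival Surv survfit survdiff
#' @export
kmLogrank <- function(time, event, group) {
  n <- length(time)
  if (length(event) != n || length(group) != n) stop("kmLogrank: length mismatch")
  group <- factor(group)
  if (nlevels(droplevels(group)) < 2L) stop("kmLogrank: need >= 2 non-empty groups")
  group <- droplevels(group)
  df <- data.frame(time = time, event = event, group = group)
  fit <- survival::survfit(Surv(time, event) ~ group, data = df)
  strata <- rep(names(fit$strata), fit$strata)
  curves <- data.frame(
    group = sub("^group=", "", strata),
    time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
    survival = fit$surv
  )
  sd <- survival::survdiff(Surv(time, event) ~ group, data = df)
  dfree <- length(sd$n) - 1L
  list(curves = curves, chi2 = unname(sd$chisq), df = dfree,
       p = stats::pchisq(unname(sd$chisq), dfree, lower.tail = FALSE))
}

#' Cox proportional hazards fit with term-level hazard ratios
#'
#' Partial-likelihood Cox fit (Efron tie handling) for univariable or
#' multivariable model specifications. Constant covariates are excluded and
#' flagged; aliased (collinear) terms are flagged. Per-term hazard ratios
#' carry Wald 95 percent intervals and p-values; the model-level p is the
#' likelihood-ratio test.
#'
#' @param time,event Survival times and 0/1 event indicators (>= 1 event).
#' @param covariates A data.frame of covariates (numeric or factor), one row
#'   per sample.
#' @return A list with \code{terms} (data.frame: term, coef, hr, ci_low,
#'   ci_high, p), \code{lrP} (model likelihood-ratio p), \code{flagged}
#'   (character vector of excluded/aliased terms) and \code{fit} (the
#'   underlying \code{coxph} object).
#' @importFrom survival coxph Surv
#' @export
coxFit <- function(time, event, covariates) {
  covariates <- as.data.frame(covariates)
  n <- length(time)
  if (length(event) != n || nrow(covariates) != n) stop("coxFit: length mismatch")
  if (sum(event == 1) < 1L) stop("coxFit: need at least one event")
  isConst <- vapply(covariates, function(v) length(unique(v)) < 2L, TRUE)
  flagged <- character(0)
  if (any(isConst)) {
    flagged <- c(flagged, paste0(names(covariates)[isConst], " (constant)"))
    covariates <- covariates[, !isConst, drop = FALSE]
  }
  if (ncol(covariates) == 0L) stop("coxFit: no non-constant covariates")
  dat <- cbind(data.frame(.time = time, .event = event), covariates)
  fml <- stats::as.formula(paste(
    "Surv(.time, .event) ~",
    paste(sprintf("`%s`", names(covariates)), collapse = " + ")))
  fit <- suppressWarnings(survival::coxph(fml, data = dat, ties = "efron"))
  co <- stats::coef(fit)
  aliased <- names(co)[is.na(co)]
  if (length(aliased)) flagged <- c(flagged, paste0(aliased, " (aliased)"))
  ok <- !is.na(co)
  se <- sqrt(diag(fit$var))[ok]
  coefs <- co[ok]
  zq <- stats::qnorm(0.975)
  terms <- data.frame(
    term = names(coefs),
    coef = unname(coefs),
    hr = exp(unname(coefs)),
    ci_low = exp(unname(coefs) - zq * se),
    ci_high = exp(unname(coefs) + zq * se),
    p = vapply(seq_along(coefs),
               function(i) waldZP(coefs[[i]], se[[i]])$p, 1.0),
    row.names = NULL
  )
  lr <- 2 * (fit$loglik[2L] - fit$loglik[1L])
  lrDf <- sum(ok)
  list(terms = terms,
       lrP = stats::pchisq(lr, lrDf, lower.tail = FALSE),
       flagged = flagged, fit = fit)
}

#' Randomly split a cohort into two halves
#'
#' Deterministic given the seed; halves are disjoint, their union is the
#' input, and their sizes differ by at most one.
#'
#' @param sampleIds Character or integer identifiers (n >= 2).
#' @param seed Integer random seed.
#' @return A list with elements \code{A} and \code{B}.
#' @export
splitCohort <- function(sampleIds, seed) {
  n <- length(sampleIds)
  if (n < 2L) stop("splitCohort: need at least 2 samples")
  perm <- withr::with_seed(as.integer(seed), sample.int(n))
  nA <- ceiling(n / 2)
  list(A = sampleIds[sort(perm[seq_len(nA)])],
       B = sampleIds[sort(perm[(nA + 1L):n])])
}

#' Per-gene univariable survival screen with BH adjustment
#'
#' Fits a univariable Cox model of survival on each gene's continuous
#' expression, adjusts p-values across genes by Benjamini-Hochberg, and
#' flags genes with adjusted p below \code{fdr} (default 0.1).
#'
#' @param expr Log2 expression matrix, genes x samples.
#' @param time,event Survival times and 0/1 event indicators aligned to the
#'   matrix columns.
#' @param fdr BH-adjusted significance threshold.
#' @return A data.frame: gene, coef, hr, ci_low, ci_high, p, p_adj,
#'   significant; rows in input gene order.
#' @export
dmfsGeneScreen <- function(expr, time, event, fdr = 0.1) {
  expr <- as.matrix(expr)
  if (ncol(expr) != length(time)) stop("dmfsGeneScreen: samples not aligned")
  rows <- lapply(seq_len(nrow(expr)), function(i) {
    res <- tryCatch(
      coxFit(time, event, data.frame(expr = expr[i, ]))$terms,
      error = function(e) NULL)
    if (is.null(res) || nrow(res) == 0L) {
      data.frame(coef = NA_real_, hr = NA_real_, ci_low = NA_real_,
                 ci_high = NA_real_, p = NA_real_)
    } else res[1L, c("coef", "hr", "ci_low", "ci_high", "p")]
  })
  out <- cbind(data.frame(gene = rownames(expr)), do.call(rbind, rows))
  rownames(out) <- NULL
  fitted <- !is.na(out$p)
  out$p_adj <- NA_real_
  out$p_adj[fitted] <- stats::p.adjust(out$p[fitted], method = "BH")
  out$significant <- !is.na(out$p_adj) & out$p_adj < fdr
  out
}

#' Stratified survival analysis of a focal gene against a cell fraction
#'
#' Within each stratum formed by the benefit label (e.g. IBE/IBD) and the
#' high/low level of an externally estimated cell fraction (high = fraction
#' quartiles 3-4 combined, low = quartiles 1-2), patients are split at the
#' within-stratum median of the focal gene's expression and the two
#' expression arms are compared by Kaplan-Meier log-rank. Strata with an
#' empty expression arm are omitted with a warning.
#'
#' @param exprRow Focal gene expression across samples.
#' @param time,event Survival times and 0/1 event indicators.
#' @param cellFraction Per-sample cell fraction score (e.g. CD8+ T cell
#'   estimate from a deconvolution tool).
#' @param benefitLabel Per-sample benefit class label (e.g. "IBE"/"IBD").
#' @return A named list (one element per stratum) of lists with \code{n},
#'   \code{chi2}, \code{p} and \code{km} (the \code{\link{kmLogrank}}
#'   curves).
#' @export
stratifiedTrem1Analysis <- function(exprRow, time, event, cellFraction,
                                    benefitLabel) {
  n <- length(exprRow)
  if (length(time) != n || length(event) != n || length(cellFraction) != n ||
      length(benefitLabel) != n) {
    stop("stratifiedTrem1Analysis: length mismatch")
  }
  fracQ <- quantileBin(cellFraction, k = 4L)
  fracLevel <- ifelse(fracQ >= 3L, "fraction_high", "fraction_low")
  out <- list()
  for (bl in sort(unique(as.character(benefitLabel)))) {
    for (fl in c("fraction_low", "fraction_high")) {
      sel <- benefitLabel == bl & fracLevel == fl
      key <- paste(bl, fl, sep = ".")
      if (sum(sel) < 4L) {
        warning("stratifiedTrem1Analysis: stratum ", key,
                " too small; omitted")
        next
      }
      arm <- ifelse(exprRow[sel] > stats::median(exprRow[sel]),
                    "expr_high", "expr_low")
      if (length(unique(arm)) < 2L) {
        warning("stratifiedTrem1Analysis: stratum ", key,
                " has an empty expression arm; omitted")
        next
      }
      km <- kmLogrank(time[sel], event[sel], arm)
      out[[key]] <- list(n = sum(sel), chi2 = km$chi2, p = km$p,
                         km = km$curves)
    }
  }
  out
}

#' Per-quartile cell fraction summary with rank correlation
#'
#' For each cell type, the mean fraction within each expression quartile,
#' centered by the grand mean of the four quartile means, plus the Spearman
#' correlation of the per-sample fraction against the quartile index.
#' Samples with a missing fraction are dropped (per cell type) with a
#' warning.
#'
#' @param fractions Numeric matrix, samples x cell types (e.g. deconvolution
#'   output), aligned to \code{quartiles}.
#' @param quartiles Integer quartile index 1..4 per sample, e.g. from
#'   \code{\link{quartileStratify}}.
#' @return A list with \code{means} (cell types x 4 matrix of centered
#'   quartile means) and \code{correlation} (data.frame: cell_type, rho, p).
#' @export
quartileCellFractionSummary <- function(fractions, quartiles) {
  fractions <- as.matrix(fractions)
  if (nrow(fractions) != length(quartiles)) {
    stop("quartileCellFractionSummary: fractions not aligned to quartiles")
  }
  if (is.null(colnames(fractions))) {
    colnames(fractions) <- paste0("cell_type_", seq_len(ncol(fractions)))
  }
  qf <- factor(quartiles, levels = 1:4)
  means <- matrix(NA_real_, ncol(fractions), 4L,
                  dimnames = list(colnames(fractions), paste0("Q", 1:4)))
  corr <- data.frame(cell_type = colnames(fractions), rho = NA_real_,
                     p = NA_real_)
  for (j in seq_len(ncol(fractions))) {
    v <- fractions[, j]
    keep <- !is.na(v)
    if (!all(keep)) {
      warning("quartileCellFractionSummary: dropped ", sum(!keep),
              " sample(s) with missing '", colnames(fractions)[j], "'")
    }
    qm <- tapply(v[keep], qf[keep], mean)
    means[j, ] <- qm - mean(qm)
    rc <- rankCorr(v[keep], as.integer(qf[keep]), method = "spearman")
    corr$rho[j] <- rc$rho
    corr$p[j] <- rc$p
  }
  list(means = means, correlation = corr)
}
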