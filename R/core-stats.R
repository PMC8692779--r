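#' Log-scale geometric mean score
#'
#' Summarizes a vector of log2 expression values as the arithmetic mean of the
#' log2 values, i.e. the log2 of the geometric mean of the linear-scale
#' intensities. Rank-equivalent to the linear geometric mean, which is all
#' that downstream tertile/quartile assignment consumes.
#'
#' @param values Numeric vector of finite log2-scale expression values.
#' @return A single numeric score on the log2 scale.
#' @examples
#' geometricMeanLog(c(2, 2, 2))      # 2
#' geometricMeanLog(c(0, 1, 2, 3))   # 1.5
#' @export
geometricMeanLog <- function(values) {
  if (length(values) == 0L) {
    stop("geometricMeanLog: empty input vector")
  }
  if (!is.numeric(values) || any(!is.finite(values))) {
    stop("geometricMeanLog: all values must be finite numerics (log2 scale)")
  }
  mean(values)
}

#' Quantile binning with deterministic tie handling
#'
#' Assigns each score to one of \code{k} population quantile bins (tertiles,
#' quartiles, ...). Bin boundaries follow the ceiling rule: the item with
#' tie-adjusted rank r falls in the smallest bin b with r <= ceiling(b*n/k).
#' Tied scores always share a bin: ranks are computed with
#' \code{ties.method = "max"} so an entire tied group is placed in the bin of
#' its last member (a tied group at the top of the distribution lands in the
#' top bin). For distinct scores this is the plain ceiling rule.
#'
#' @param scores Numeric vector (no NAs).
#' @param k Number of bins, >= 2.
#' @return Integer vector of bin indices in 1..k, lowest scores in bin 1.
#' @examples
#' quantileBin(c(1, 2, 3), k = 3)     # 1 2 3
#' quantileBin(c(5, 5, 5, 1), k = 2)  # 2 2 2 1
#' @export
quantileBin <- function(scores, k) {
  if (!is.numeric(scores) || any(is.na(scores))) {
    stop("quantileBin: scores must be numeric without NAs")
  }
  k <- as.integer(k)
  if (k < 2L) stop("quantileBin: k must be >= 2")
  n <- length(scores)
  if (n < k) stop("quantileBin: need at least k observations (n=", n, ", k=", k, ")")
  bounds <- ceiling(seq_len(k) * n / k)
  r <- rank(scores, ties.method = "max")
  bins <- findInterval(r - 1L, bounds) + 1L
  as.integer(bins)
}

#' Signed Wald statistic and two-sided p-value
#'
#' Computes the signed Wald Z as the ratio of a regression coefficient to its
#' standard error, the corresponding chi-square statistic (Z squared), and the
#' two-sided standard-normal tail probability. The sign of Z is retained so
#' that antagonistic (negative) interactions can be ranked.
#'
#' @param coef Regression coefficient.
#' @param se Standard error, strictly positive.
#' @return A list with components \code{z}, \code{chi2} and \code{p}.
#' @examples
#' waldZP(0.5, 0.25)$z    # 2
#' waldZP(-3.3, 1)$p      # ~0.000967
#' @export
waldZP <- function(coef, se) {
  if (!is.numeric(se) || length(se) != 1L || is.na(se) || se <= 0) {
    stop("waldZP: se must be a single positive number")
  }
  if (!is.numeric(coef) || length(coef) != 1L || is.na(coef)) {
    stop("waldZP: coef must be a single finite number")
  }
  z <- coef / se
  list(z = z, chi2 = z^2, p = 2 * stats::pnorm(-abs(z)))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Standard step-up BH adjustment with a significance call at a stated
#' threshold.
#'
#' @param pRaw Numeric vector of raw p-values in [0, 1].
#' @param alpha Significance threshold applied to the adjusted values.
#' @return A data.frame with columns \code{p_raw}, \code{p_adj} and
#'   \code{significant}.
#' @export
bhAdjust <- function(pRaw, alpha = 0.05) {
  if (length(pRaw) == 0L) stop("bhAdjust: empty p-value vector")
  if (!is.numeric(pRaw) || any(is.na(pRaw)) || any(pRaw < 0 | pRaw > 1)) {
    stop("bhAdjust: p-values must lie in [0, 1]")
  }
  pAdj <- stats::p.adjust(pRaw, method = "BH")
  data.frame(p_raw = pRaw, p_adj = pAdj, significant = pAdj < alpha)
}

#' Yates-corrected chi-square test for a 2x2 table
#'
#' Chi-square statistic with continuity correction, with the correction
#' clamped so that cells where |O - E| < 0.5 contribute zero rather than an
#' inflated term; p-value from the chi-square distribution with 1 df.
#'
#' @param tab A 2x2 matrix of non-negative counts (group x outcome).
#' @return A list with \code{stat} and \code{p}.
#' @export
chi2Yates <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2L, 2L))) stop("chi2Yates: table must be 2x2")
  if (any(tab < 0) || any(!is.finite(tab))) stop("chi2Yates: counts must be non-negative")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("chi2Yates: all row and column margins must be positive")
  }
  # chisq.test's Yates correction uses min(0.5, |O - E|), i.e. the clamped form
  res <- suppressWarnings(stats::chisq.test(tab, correct = TRUE))
  list(stat = unname(res$statistic), p = unname(res$p.value))
}

#' Rank (Spearman) or Pearson correlation with t-approximation p-value
#'
#' Spearman rho uses average ranks for ties. The p-value comes from the
#' t-approximation t = rho * sqrt((n-2)/(1-rho^2)) on n-2 df. A constant
#' input vector leaves the correlation undefined; the result is flagged
#' rather than silently returning a number.
#'
#' @param x,y Numeric vectors of equal length, n >= 3.
#' @param method "spearman" (default) or "pearson".
#' @return A list with \code{rho}, \code{p} and \code{defined} (FALSE when a
#'   vector is constant).
#' @export
rankCorr <- function(x, y, method = c("spearman", "pearson")) {
  method <- match.arg(method)
  if (length(x) != length(y)) stop("rankCorr: x and y must have equal length")
  n <- length(x)
  if (n < 3L) stop("rankCorr: need at least 3 observations")
  if (any(!is.finite(x)) || any(!is.finite(y))) stop("rankCorr: non-finite values")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(rho = NA_real_, p = NA_real_, defined = FALSE))
  }
  if (method == "spearman") {
    rho <- stats::cor(rank(x), rank(y))
  } else {
    rho <- stats::cor(x, y)
  }
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(rho = rho, p = p, defined = TRUE)
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Exact enumeration (via the Wilcoxon distribution) when both groups have at
#' most \code{exactMax} observations and the pooled data carry no ties;
#' otherwise the normal approximation with the usual tie correction and no
#' continuity correction (so identical groups give p = 1).
#'
#' @param a,b Non-empty numeric vectors.
#' @param exactMax Largest per-group size for the exact branch (default 8).
#' @return A list with \code{stat} (the Mann-Whitney U of \code{a}), \code{p}
#'   and \code{exact}.
#' @export
wilcoxonRankSum <- function(a, b, exactMax = 8L) {
  if (length(a) == 0L || length(b) == 0L) {
    stop("wilcoxonRankSum: both groups must be non-empty")
  }
  pooled <- c(a, b)
  if (any(!is.finite(pooled))) stop("wilcoxonRankSum: non-finite values")
  if (length(unique(pooled)) == 1L) {
    # rank variance is zero; no evidence either way
    return(list(stat = length(a) * length(b) / 2, p = 1, exact = FALSE))
  }
  useExact <- length(a) <= exactMax && length(b) <= exactMax &&
    !anyDuplicated(pooled)
  res <- suppressWarnings(
    stats::wilcox.test(a, b, exact = useExact, correct = FALSE)
  )
  list(stat = unname(res$statistic), p = res$p.value, exact = useExact)
}

#' Kruskal-Wallis rank test across groups
#'
#' Tie-corrected H statistic with chi-square p-value. The degenerate case in
#' which every observation is identical (H undefined by the tie correction)
#' returns H = 0, p = 1.
#'
#' @param groups A list of two or more non-empty numeric vectors.
#' @return A list with \code{H}, \code{p} and \code{df}.
#' @export
kruskalWallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L) {
    stop("kruskalWallis: need a list of at least 2 groups")
  }
  if (any(vapply(groups, length, 1L) == 0L)) {
    stop("kruskalWallis: all groups must be non-empty")
  }
  values <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), vapply(groups, length, 1L)))
  if (length(unique(values)) == 1L) {
    return(list(H = 0, p = 1, df = length(groups) - 1L))
  }
  res <- stats::kruskal.test(values, g)
  list(H = unname(res$statistic), p = res$p.value,
       df = unname(res$parameter))
}

#' Hypergeometric over-representation test
#'
#' One-sided upper-tail hypergeometric probability P(X >= overlap) for the
#' overlap between a hit list and a category inside a gene universe. A
#' generic enrichment stand-in for annotation-category over-representation.
#'
#' @param hits Character vector of hit genes (subset of \code{universe}).
#' @param category Character vector of category genes (subset of
#'   \code{universe}).
#' @param universe Character vector of all testable genes.
#' @return A list with \code{overlap} and \code{p}.
#' @export
overRepresentation <- function(hits, category, universe) {
  hits <- unique(hits); category <- unique(category); universe <- unique(universe)
  if (!all(hits %in% universe)) {
    stop("overRepresentation: hits must be a subset of the universe")
  }
  if (!all(category %in% universe)) {
    stop("overRepresentation: category must be a subset of the universe")
  }
  overlap <- length(intersect(hits, category))
  p <- stats::phyper(overlap - 1L, length(category),
                     length(universe) - length(category), length(hits),
                     lower.tail = FALSE)
  list(overlap = overlap, p = p)
}
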