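#' Wilcoxon differential expression on a log2 expression matrix
#'
#' Per-gene two-sided Wilcoxon rank-sum test between two sample groups of a
#' log2-scale expression matrix (e.g. a treated-versus-control activation
#' experiment), BH-adjusted, significant at adjusted p below \code{fdr}.
#' The effect is the difference of group means on the log2 scale (a log2
#' fold change); positive means higher in the selected group.
#'
#' @param expr Log2 expression matrix, genes x samples.
#' @param group1 Logical vector selecting the group of interest (e.g.
#'   treated samples).
#' @param fdr BH significance threshold (default 0.01).
#' @return A data.frame: gene, effect, p, p_adj, significant.
#' @export
deExpressionGroups <- function(expr, group1, fdr = 0.01) {
  expr <- as.matrix(expr)
  if (length(group1) != ncol(expr)) stop("deExpressionGroups: one label per sample")
  group1 <- as.logical(group1)
  if (!any(group1) || all(group1)) stop("deExpressionGroups: both groups must be non-empty")
  p <- vapply(seq_len(nrow(expr)), function(i) {
    wilcoxonRankSum(expr[i, group1], expr[i, !group1])$p
  }, 1.0)
  adj <- bhAdjust(p, alpha = fdr)
  data.frame(gene = rownames(expr),
             effect = rowMeans(expr[, group1, drop = FALSE]) -
               rowMeans(expr[, !group1, drop = FALSE]),
             p = p, p_adj = adj$p_adj, significant = adj$significant,
             row.names = NULL)
}
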