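#' @importFrom SingleCellExperiment SingleCellExperiment
#' @importFrom SummarizedExperiment assay colData rowData
NULL

.counts <- function(sce) {
  SummarizedExperiment::assay(sce, "counts")
}

#' Quality-control filter for single-cell count matrices
#'
#' Removes cells that express fewer than \code{minGenes} distinct genes
#' (count >= 1) or whose mitochondrial reads exceed \code{maxMitoFrac} of the
#' total UMI count. Both boundaries are retained: a cell with exactly 400
#' detected genes and exactly 20 percent mitochondrial content is kept.
#' Mitochondrial genes are identified by the "MT-" prefix convention unless
#' a logical \code{mito} column is present in \code{rowData}.
#'
#' @param sce A \code{SingleCellExperiment} with a \code{counts} assay.
#' @param minGenes Minimum number of detected genes (default 400).
#' @param maxMitoFrac Maximum mitochondrial count fraction (default 0.20).
#' @return The filtered \code{SingleCellExperiment}; idempotent.
#' @export
qcFilter <- function(sce, minGenes = 400L, maxMitoFrac = 0.20) {
  counts <- .counts(sce)
  mito <- if ("mito" %in% colnames(rowData(sce))) {
    rowData(sce)$mito
  } else {
    grepl("^MT-", rownames(sce))
  }
  detected <- Matrix::colSums(counts >= 1)
  total <- Matrix::colSums(counts)
  mitoFrac <- ifelse(total > 0,
                     Matrix::colSums(counts[mito, , drop = FALSE]) / total, 0)
  keep <- detected >= minGenes & mitoFrac <= maxMitoFrac
  if (!any(keep)) message("qcFilter: no cell passes QC")
  sce[, keep]
}

#' Library-size normalized expression
#'
#' Counts scaled to a fixed per-cell total (default 10,000) then log1p
#' transformed. Used for effect sizes and group comparisons; positivity
#' calls always use raw counts.
#'
#' @param sce A \code{SingleCellExperiment} with a \code{counts} assay.
#' @param scale Target per-cell total.
#' @return A dense or sparse matrix of normalized values (genes x cells).
#' @export
normalizeCells <- function(sce, scale = 1e4) {
  counts <- .counts(sce)
  total <- Matrix::colSums(counts)
  total[total == 0] <- 1
  norm <- counts %*% Matrix::Diagonal(x = scale / total)
  colnames(norm) <- colnames(counts)
  log1p(norm)
}

#' Marker positivity per cell
#'
#' A cell is positive for a gene iff its raw count is at least 1, i.e. any
#' positive linear normalized expression value.
#'
#' @param sce A \code{SingleCellExperiment}.
#' @param gene Gene identifier present in the object.
#' @return Logical vector, one entry per cell.
#' @export
positivity <- function(sce, gene) {
  if (!gene %in% rownames(sce)) stop("positivity: gene '", gene, "' absent")
  as.vector(.counts(sce)[gene, ] >= 1)
}

#' Wilcoxon differential expression between two cell groups
#'
#' Per-gene two-sided Wilcoxon rank-sum test on library-size-normalized,
#' log1p expression, BH-adjusted across genes, significant at adjusted
#' p below \code{fdr} (default 0.01). The effect is the log2 fold change of
#' the normalized (counts-per-\code{scale}) group means with a pseudocount
#' of 1; positive effect means higher in the first group level.
#'
#' @param sce A \code{SingleCellExperiment}.
#' @param groups Factor-like with exactly two levels, one per cell; the
#'   first level is the group of interest (e.g. marker-positive).
#' @param fdr BH significance threshold.
#' @param scale Normalization target total.
#' @return A data.frame: gene, effect, p, p_adj, significant.
#' @export
deBetweenGroups <- function(sce, groups, fdr = 0.01, scale = 1e4) {
  groups <- as.factor(groups)
  if (nlevels(groups) != 2L) stop("deBetweenGroups: need exactly 2 groups")
  if (length(groups) != ncol(sce)) stop("deBetweenGroups: one label per cell")
  sizes <- table(groups)
  if (any(sizes < 3L)) stop("deBetweenGroups: both groups need >= 3 cells")
  lognorm <- as.matrix(normalizeCells(sce, scale = scale))
  linear <- expm1(lognorm)
  g1 <- groups == levels(groups)[1L]
  m1 <- rowMeans(linear[, g1, drop = FALSE])
  m2 <- rowMeans(linear[, !g1, drop = FALSE])
  p <- vapply(seq_len(nrow(lognorm)), function(i) {
    wilcoxonRankSum(lognorm[i, g1], lognorm[i, !g1])$p
  }, 1.0)
  adj <- bhAdjust(p, alpha = fdr)
  data.frame(gene = rownames(sce),
             effect = log2((m1 + 1) / (m2 + 1)),
             p = p, p_adj = adj$p_adj, significant = adj$significant,
             row.names = NULL)
}

#' Compare a target gene between marker-positive and -negative cells
#'
#' Groups cells by raw-count positivity for the marker gene and compares the
#' target gene's normalized expression between the groups with the Wilcoxon
#' rank-sum test.
#'
#' @param sce A \code{SingleCellExperiment} (typically pre-subset to one
#'   compartment, e.g. myeloid cells).
#' @param markerGene,targetGene Gene identifiers.
#' @return A list with \code{positive} and \code{negative} expression
#'   vectors, group sizes \code{nPositive}/\code{nNegative}, \code{stat} and
#'   \code{p}.
#' @export
markerGroupCompare <- function(sce, markerGene, targetGene) {
  pos <- positivity(sce, markerGene)
  if (!targetGene %in% rownames(sce)) {
    stop("markerGroupCompare: gene '", targetGene, "' absent")
  }
  if (!any(pos) || all(pos)) {
    stop("markerGroupCompare: marker-positive or -negative group is empty")
  }
  target <- as.vector(normalizeCells(sce)[targetGene, ])
  w <- wilcoxonRankSum(target[pos], target[!pos])
  list(positive = target[pos], negative = target[!pos],
       nPositive = sum(pos), nNegative = sum(!pos),
       stat = w$stat, p = w$p)
}

#' Assemble the cross-dataset target gene panel
#'
#' A gene joins the panel iff it is significantly up-regulated (BH-adjusted
#' p below the table's threshold, positive effect) in focal-gene-positive
#' versus -negative myeloid cells in BOTH tumor single-cell DE tables AND
#' significantly induced in the activation (treated versus control) DE
#' table. The result is invariant to gene order and to swapping the two
#' tumor tables.
#'
#' @param deTumorA,deTumorB,deActivation Data frames as returned by
#'   \code{\link{deBetweenGroups}} (columns gene, effect, significant).
#' @return A \code{\link{TargetPanel-class}} object over the shared genes.
#' @importFrom S4Vectors DataFrame
#' @export
assemblePanel <- function(deTumorA, deTumorB, deActivation) {
  for (d in list(deTumorA, deTumorB, deActivation)) {
    if (!all(c("gene", "effect", "significant") %in% colnames(d))) {
      stop("assemblePanel: DE tables need columns gene, effect, significant")
    }
  }
  shared <- Reduce(intersect, list(deTumorA$gene, deTumorB$gene,
                                   deActivation$gene))
  if (length(shared) == 0L) stop("assemblePanel: no shared genes across tables")
  shared <- sort(shared)
  up <- function(d) {
    idx <- match(shared, d$gene)
    d$significant[idx] & d$effect[idx] > 0
  }
  ev <- DataFrame(gene = shared,
                  up_tumorA = up(deTumorA),
                  up_tumorB = up(deTumorB),
                  up_activation = up(deActivation))
  ev$member <- ev$up_tumorA & ev$up_tumorB & ev$up_activation
  new("TargetPanel", genes = ev$gene[ev$member], evidence = ev,
      direction = "up")
}

#' @rdname TargetPanel-class
#' @export
setMethod("panelGenes", "TargetPanel", function(x) x@genes)

#' @rdname TargetPanel-class
#' @export
setMethod("panelEvidence", "TargetPanel", function(x) x@evidence)

#' @rdname TargetPanel-class
#' @param object A \code{TargetPanel}.
#' @export
setMethod("show", "TargetPanel", function(object) {
  cat("TargetPanel:", length(object@genes), "member gene(s) of",
      nrow(object@evidence), "shared genes (direction:", object@direction,
      ")\n")
  if (length(object@genes)) {
    cat(" ", paste(object@genes, collapse = ", "), "\n")
  }
})

#' Per-tumor focal-gene positivity and panel expression profile
#'
#' For each tumor: the percentage of focal-gene-positive cells within the
#' myeloid compartment, and the mean normalized panel-gene expression within
#' each compartment (myeloid, cancer, fibroblast). Tumors are returned in
#' descending order of the positivity percentage. Tumors without myeloid
#' cells carry an undefined (NA) frequency and are flagged.
#'
#' @param sce A \code{SingleCellExperiment} whose \code{colData} carries
#'   \code{tumor_id}, \code{cell_type} and optionally \code{subtype}.
#' @param panel A \code{\link{TargetPanel-class}} or character vector of
#'   panel genes.
#' @param focalGene Focal gene identifier (default "TREM1").
#' @param compartments Compartment labels to profile.
#' @return A data.frame: tumor_id, subtype, n_myeloid, pct_positive,
#'   one panel-mean column per compartment, and \code{flagged}.
#' @export
tumorProfile <- function(sce, panel, focalGene = "TREM1",
                         compartments = c("myeloid", "cancer", "fibroblast")) {
  genes <- if (is(panel, "TargetPanel")) panelGenes(panel) else as.character(panel)
  genes <- intersect(genes, rownames(sce))
  if (length(genes) == 0L) stop("tumorProfile: no panel gene present")
  cd <- as.data.frame(colData(sce))
  if (!all(c("tumor_id", "cell_type") %in% colnames(cd))) {
    stop("tumorProfile: colData needs tumor_id and cell_type")
  }
  pos <- positivity(sce, focalGene)
  lognorm <- normalizeCells(sce)
  tumors <- unique(as.character(cd$tumor_id))
  rows <- lapply(tumors, function(tu) {
    inTumor <- cd$tumor_id == tu
    my <- inTumor & cd$cell_type == "myeloid"
    pct <- if (any(my)) 100 * mean(pos[my]) else NA_real_
    panelMeans <- vapply(compartments, function(cp) {
      sel <- inTumor & cd$cell_type == cp
      if (!any(sel)) return(NA_real_)
      mean(as.matrix(lognorm[genes, sel, drop = FALSE]))
    }, 1.0)
    names(panelMeans) <- paste0("panel_mean_", compartments)
    subtype <- if ("subtype" %in% colnames(cd)) {
      as.character(cd$subtype[inTumor][1L])
    } else NA_character_
    cbind(data.frame(tumor_id = tu, subtype = subtype,
                     n_myeloid = sum(my), pct_positive = pct,
                     flagged = !any(my)),
          as.data.frame(t(panelMeans)))
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$pct_positive, out$tumor_id, na.last = TRUE), ]
  rownames(out) <- NULL
  out
}

#' Compare per-tumor positivity frequencies across subtypes
#'
#' Kruskal-Wallis test of the per-tumor focal-gene positivity percentage
#' across tumor subtypes, plus pairwise Wilcoxon rank-sum contrasts.
#' Subtypes with fewer than two tumors are excluded with a warning.
#'
#' @param profiles Output of \code{\link{tumorProfile}} (columns subtype and
#'   pct_positive), or a data.frame with those columns.
#' @return A list with \code{H}, \code{p}, \code{groups} (named list of
#'   frequency vectors) and \code{pairwise} (data.frame: group1, group2,
#'   stat, p).
#' @export
subtypeFrequencyTest <- function(profiles) {
  if (!all(c("subtype", "pct_positive") %in% colnames(profiles))) {
    stop("subtypeFrequencyTest: need columns subtype and pct_positive")
  }
  keep <- !is.na(profiles$pct_positive) & !is.na(profiles$subtype)
  groups <- split(profiles$pct_positive[keep],
                  as.character(profiles$subtype[keep]))
  small <- vapply(groups, length, 1L) < 2L
  if (any(small)) {
    warning("subtypeFrequencyTest: excluded subtype(s) with < 2 tumors: ",
            paste(names(groups)[small], collapse = ", "))
    groups <- groups[!small]
  }
  if (length(groups) < 2L) stop("subtypeFrequencyTest: need >= 2 usable subtypes")
  kw <- kruskalWallis(groups)
  combs <- utils::combn(names(groups), 2L)
  pairwise <- do.call(rbind, lapply(seq_len(ncol(combs)), function(i) {
    a <- combs[1L, i]; b <- combs[2L, i]
    w <- wilcoxonRankSum(groups[[a]], groups[[b]])
    data.frame(group1 = a, group2 = b, stat = w$stat, p = w$p)
  }))
  list(H = kw$H, p = kw$p, groups = groups, pairwise = pairwise)
}
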