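#' Synthetic bulk expression cohort with latent immune structure
#'
#' Generates a log2-scale expression matrix (genes x samples) with three
#' correlated immune-signature gene blocks driven by latent per-sample
#' factors, a focal myeloid gene co-expressed with a myeloid cluster via a
#' shared latent factor, and log-normal background genes. All randomness is
#' a pure function of \code{seed}.
#'
#' Defaults emulate a neoadjuvant microarray cohort: 400 samples, 2,000
#' genes, inter-signature factor correlation 0.6 (immune signatures are
#' strongly positively correlated in real tumors, which yields realistic
#' FID/WID/PID proportions rather than the independence limit), and a
#' focal-cluster loading high enough that focal-vs-cluster gene correlations
#' exceed 0.6.
#'
#' @param nSamples Number of samples (>= 30).
#' @param nGenes Total number of genes.
#' @param seed Integer seed.
#' @param factorCor Pairwise correlation of the three signature factors.
#' @param myeloidCor Correlation between the myeloid factor and the M/D
#'   signature factor.
#' @param sigGenesPer Genes per signature block.
#' @param nClusterGenes Myeloid cluster genes co-expressed with the focal
#'   gene.
#' @param focalGene Focal gene identifier.
#' @param sigLoading,clusterLoading Factor loadings.
#' @param noiseSd,clusterNoiseSd Residual standard deviations.
#' @return A list with \code{expr} (matrix), \code{signatureSets} (named
#'   list for \code{\link{scoreSignatures}}), \code{age} (per-sample years)
#'   and \code{truth} (latent factors and planted gene groups).
#' @export
makeBulkCohort <- function(nSamples = 400L, nGenes = 2000L, seed = 1L,
                           factorCor = 0.6, myeloidCor = 0.3,
                           sigGenesPer = 10L, nClusterGenes = 10L,
                           focalGene = "TREM1", sigLoading = 1.0,
                           clusterLoading = 1.2, noiseSd = 0.7,
                           clusterNoiseSd = 0.5) {
  if (nSamples < 30L) stop("makeBulkCohort: need at least 30 samples")
  nSpecial <- 3L * sigGenesPer + 1L + nClusterGenes
  if (nGenes <= nSpecial) stop("makeBulkCohort: nGenes too small for the planted blocks")
  sigNames <- list(tnk = sprintf("TNK_%02d", seq_len(sigGenesPer)),
                   bp = sprintf("BP_%02d", seq_len(sigGenesPer)),
                   md = sprintf("MD_%02d", seq_len(sigGenesPer)))
  clusterGenes <- sprintf("MYEL_%02d", seq_len(nClusterGenes))
  if (any(duplicated(c(unlist(sigNames), focalGene, clusterGenes)))) {
    stop("makeBulkCohort: planted gene blocks overlap")
  }
  bgGenes <- sprintf("G%04d", seq_len(nGenes - nSpecial))
  genes <- c(unlist(sigNames, use.names = FALSE), focalGene, clusterGenes,
             bgGenes)
  withr::with_seed(as.integer(seed), {
    # latent factors: three signature factors with exchangeable correlation,
    # plus a myeloid factor tied to the M/D factor
    sigma <- matrix(factorCor, 3L, 3L); diag(sigma) <- 1
    zRaw <- matrix(stats::rnorm(nSamples * 3L), nSamples, 3L)
    factors <- zRaw %*% chol(sigma)
    colnames(factors) <- c("tnk", "bp", "md")
    myeloid <- myeloidCor * factors[, "md"] +
      sqrt(1 - myeloidCor^2) * stats::rnorm(nSamples)
    mu <- stats::rnorm(nGenes, mean = 7, sd = 1)
    names(mu) <- genes
    mu[c(focalGene, clusterGenes)] <- stats::rnorm(1L + nClusterGenes,
                                                   mean = 8.5, sd = 0.3)
    expr <- matrix(stats::rnorm(nGenes * nSamples, sd = noiseSd),
                   nGenes, nSamples, dimnames = list(genes, NULL))
    for (k in seq_along(sigNames)) {
      idx <- sigNames[[k]]
      expr[idx, ] <- expr[idx, ] +
        rep(sigLoading * factors[, k], each = length(idx))
    }
    clusterAll <- c(focalGene, clusterGenes)
    expr[clusterAll, ] <- matrix(stats::rnorm(length(clusterAll) * nSamples,
                                              sd = clusterNoiseSd),
                                 length(clusterAll), nSamples) +
      rep(clusterLoading * myeloid, each = length(clusterAll))
    expr <- expr + mu
    colnames(expr) <- sprintf("S%04d", seq_len(nSamples))
    age <- stats::runif(nSamples, 30, 70)
  })
  list(expr = expr, signatureSets = sigNames, age = age,
       truth = list(factors = factors, myeloid = myeloid,
                    focalGene = focalGene, clusterGenes = clusterGenes,
                    signatureSets = sigNames, seed = as.integer(seed)))
}

#' Synthetic binary chemotherapy response with planted interaction
#'
#' Bernoulli response under the logistic model
#' logit(p) = b0 + bSub*ord + bAge*age + bGene*geneHigh +
#' bInt*geneHigh*ord, where ord is the ordinal subclass (PID=0, WID=1,
#' FID=2). A negative \code{bInt} plants an antagonistic gene-by-subclass
#' interaction.
#'
#' @param subclass FID/WID/PID labels per sample.
#' @param geneHigh Binary 0/1 focal gene level per sample.
#' @param age Ages in years.
#' @param betas Named numeric vector with elements b0, bSub, bAge, bGene,
#'   bInt.
#' @param seed Integer seed.
#' @return Integer 0/1 response vector.
#' @export
makeResponse <- function(subclass, geneHigh, age,
                         betas = c(b0 = -1.2, bSub = 0.8, bAge = 0,
                                   bGene = 0, bInt = 0),
                         seed = 1L) {
  n <- length(subclass)
  if (length(geneHigh) != n || length(age) != n) {
    stop("makeResponse: input lengths differ")
  }
  need <- c("b0", "bSub", "bAge", "bGene", "bInt")
  if (!all(need %in% names(betas))) {
    stop("makeResponse: betas must name ", paste(need, collapse = ", "))
  }
  ord <- subclassOrdinal(subclass)
  eta <- betas[["b0"]] + betas[["bSub"]] * ord + betas[["bAge"]] * age +
    betas[["bGene"]] * geneHigh + betas[["bInt"]] * geneHigh * ord
  prob <- stats::plogis(eta)
  withr::with_seed(as.integer(seed), stats::rbinom(n, 1L, prob))
}

#' Synthetic proportional-hazards survival records
#'
#' Exponential event times with hazard baseline * exp(sum(logHR * covariate))
#' and independent uniform censoring on (0, censorMax]. Apply
#' \code{\link{prepareEndpoint}} downstream for the horizon rule.
#'
#' @param covariates Numeric matrix or data.frame, samples x covariates.
#' @param logHR Named log hazard ratios aligned to the covariate columns.
#' @param baseline Baseline hazard (events per year).
#' @param censorMax Upper bound of the uniform censoring time.
#' @param seed Integer seed.
#' @return A data.frame with \code{time} and \code{event}.
#' @export
makeSurvival <- function(covariates, logHR, baseline = 0.08,
                         censorMax = 12, seed = 1L) {
  covariates <- as.matrix(covariates)
  if (ncol(covariates) != length(logHR)) {
    stop("makeSurvival: logHR must match covariate columns")
  }
  lp <- as.vector(covariates %*% logHR)
  withr::with_seed(as.integer(seed), {
    t <- stats::rexp(nrow(covariates), rate = baseline * exp(lp))
    cens <- stats::runif(nrow(covariates), 0, censorMax)
    data.frame(time = pmin(t, cens), event = as.integer(t <= cens))
  })
}

#' Synthetic multi-tumor single-cell count matrix
#'
#' Negative-binomial counts for cells from several tumors, each split into
#' myeloid / cancer / fibroblast compartments with dedicated marker
#' programs. Within the myeloid compartment a configurable per-tumor
#' fraction of cells expresses the focal gene (raw count >= 1 by
#' construction), and planted target genes are up-shifted by
#' \code{targetFold} in focal-positive cells. The per-tumor positive
#' fraction follows a subtype-tied gradient. Mitochondrial content is
#' modelled by a small block of "MT-" genes.
#'
#' @param nTumors Number of tumors.
#' @param cellsPerTumor Cells per tumor; compartment sizes are exact
#'   (proportions 0.4/0.4/0.2).
#' @param nGenes Gene universe size (includes focal, targets, markers, MT
#'   block).
#' @param seed Integer seed.
#' @param subtypes Subtype labels recycled across tumors.
#' @param posFracBySubtype Named per-subtype focal-positive fraction within
#'   myeloid cells.
#' @param focalGene Focal gene identifier.
#' @param targetGenes Planted target genes up-regulated in focal-positive
#'   myeloid cells.
#' @param extraUpGenes Genes up-shifted in focal-positive cells that are NOT
#'   activation-induced elsewhere (tumor-only evidence), may be character(0).
#' @param neutralGenes Genes included in the universe at baseline expression
#'   with no planted regulation (e.g. activation-only decoys).
#' @param targetFold Linear fold change planted on targets in focal-positive
#'   cells.
#' @param nbSize Negative-binomial size (dispersion) parameter.
#' @return A list with \code{sce} (a \code{SingleCellExperiment}: counts,
#'   colData tumor_id/cell_type/subtype, rowData mito) and \code{truth}.
#' @export
makeSinglecellTumors <- function(nTumors = 3L, cellsPerTumor = 500L,
                                 nGenes = 1000L, seed = 1L,
                                 subtypes = c("TNBC", "ER+", "HER2+"),
                                 posFracBySubtype = c("TNBC" = 0.45,
                                                      "ER+" = 0.15,
                                                      "HER2+" = 0.30),
                                 focalGene = "TREM1",
                                 targetGenes = c("IL1B", "CCL7", "CXCL3",
                                                 "IL1RN", "INHBA", "IL6",
                                                 "IL8", "CCL2"),
                                 extraUpGenes = character(0),
                                 neutralGenes = character(0),
                                 targetFold = 4, nbSize = 2) {
  compartments <- c(myeloid = 0.4, cancer = 0.4, fibroblast = 0.2)
  nMito <- 10L
  markerPer <- 15L
  special <- c(focalGene, targetGenes, extraUpGenes, neutralGenes)
  nBg <- nGenes - length(special) - nMito
  if (nBg < 3L * markerPer + 10L) stop("makeSinglecellTumors: nGenes too small")
  bg <- sprintf("BG_%04d", seq_len(nBg))
  mito <- sprintf("MT-G%02d", seq_len(nMito))
  genes <- c(special, bg, mito)
  markerSets <- list(myeloid = bg[seq_len(markerPer)],
                     cancer = bg[markerPer + seq_len(markerPer)],
                     fibroblast = bg[2L * markerPer + seq_len(markerPer)])
  tumorSubtype <- rep_len(subtypes, nTumors)
  posFrac <- unname(posFracBySubtype[tumorSubtype])
  if (any(is.na(posFrac))) stop("makeSinglecellTumors: posFracBySubtype must cover all subtypes")
  nComp <- round(cellsPerTumor * compartments)
  nComp[1L] <- cellsPerTumor - sum(nComp[-1L])  # realize sizes exactly
  withr::with_seed(as.integer(seed), {
    baseMu <- stats::rlnorm(length(genes), meanlog = log(1.5), sdlog = 0.8)
    names(baseMu) <- genes
    baseMu[mito] <- 1.5
    baseMu[c(focalGene, targetGenes, extraUpGenes)] <- 0.5
    counts <- NULL
    meta <- NULL
    truthPos <- list()
    for (tu in seq_len(nTumors)) {
      cellTypes <- rep(names(nComp), nComp)
      nc <- length(cellTypes)
      mu <- matrix(baseMu, length(genes), nc, dimnames = list(genes, NULL))
      for (cp in names(markerSets)) {
        mu[markerSets[[cp]], cellTypes == cp] <-
          mu[markerSets[[cp]], cellTypes == cp] * 6
      }
      myel <- cellTypes == "myeloid"
      pos <- rep(FALSE, nc)
      pos[myel] <- stats::runif(sum(myel)) < posFrac[tu]
      upGenes <- c(targetGenes, extraUpGenes)
      mu[upGenes, pos] <- mu[upGenes, pos] * targetFold
      cnt <- matrix(stats::rnbinom(length(genes) * nc,
                                   mu = as.vector(mu), size = nbSize),
                    length(genes), nc, dimnames = list(genes, NULL))
      # focal gene expression planted directly so the positive fraction is
      # exactly the drawn set: positives are zero-truncated, negatives zero
      cnt[focalGene, ] <- 0L
      cnt[focalGene, pos] <- stats::rnbinom(sum(pos), mu = 3, size = nbSize) + 1L
      sparseFocal <- !myel & stats::runif(nc) < 0.02
      cnt[focalGene, sparseFocal] <- 1L
      counts <- cbind(counts, cnt)
      meta <- rbind(meta, data.frame(
        tumor_id = sprintf("T%02d", tu), cell_type = cellTypes,
        subtype = tumorSubtype[tu]))
      truthPos[[tu]] <- pos
    }
  })
  barcodes <- sprintf("CELL_%05d", seq_len(ncol(counts)))
  colnames(counts) <- barcodes
  rownames(meta) <- barcodes
  sce <- SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = methods::as(counts, "CsparseMatrix")),
    colData = S4Vectors::DataFrame(meta))
  SummarizedExperiment::rowData(sce)$mito <- grepl("^MT-", rownames(sce))
  list(sce = sce,
       truth = list(focalGene = focalGene, targetGenes = targetGenes,
                    extraUpGenes = extraUpGenes, markerSets = markerSets,
                    posFrac = stats::setNames(posFrac,
                                              sprintf("T%02d", seq_len(nTumors))),
                    positive = truthPos, seed = as.integer(seed)))
}

#' Synthetic paired activation experiment
#'
#' Matched treated/control log2 expression profiles with correlated
#' per-subject baselines and a planted set of induced genes (additive log2
#' fold change in the treated arm). Defaults emulate an 11-pairs-per-arm
#' monocyte activation design with strong (8-fold) cytokine induction, the
#' magnitude typical of agonist-antibody receptor activation.
#'
#' @param nPairs Number of subject pairs (>= 3).
#' @param nGenes Gene universe size (ignored when \code{geneNames} given).
#' @param seed Integer seed.
#' @param inducedGenes Genes induced in the treated arm.
#' @param log2Fold Planted log2 fold change.
#' @param geneNames Optional explicit gene universe (must contain
#'   \code{inducedGenes}).
#' @param subjectSd,noiseSd Baseline and residual standard deviations.
#' @return A list with \code{expr} (genes x 2*nPairs log2 matrix),
#'   \code{treated} (logical per column), \code{subject} (pair id per
#'   column) and \code{truth}.
#' @export
makeActivationPairs <- function(nPairs = 11L, nGenes = 1000L, seed = 1L,
                                inducedGenes = character(0), log2Fold = 3,
                                geneNames = NULL, subjectSd = 0.5,
                                noiseSd = 0.5) {
  if (nPairs < 3L) stop("makeActivationPairs: need at least 3 pairs")
  if (is.null(geneNames)) {
    nBg <- nGenes - length(inducedGenes)
    if (nBg < 1L) stop("makeActivationPairs: nGenes too small")
    geneNames <- c(inducedGenes, sprintf("ACT_BG_%04d", seq_len(nBg)))
  }
  if (!all(inducedGenes %in% geneNames)) {
    stop("makeActivationPairs: inducedGenes must be in geneNames")
  }
  ng <- length(geneNames)
  withr::with_seed(as.integer(seed), {
    mu <- stats::rnorm(ng, mean = 7, sd = 1.5)
    subjBase <- stats::rnorm(nPairs, sd = subjectSd)
    control <- matrix(mu, ng, nPairs) +
      matrix(subjBase, ng, nPairs, byrow = TRUE) +
      matrix(stats::rnorm(ng * nPairs, sd = noiseSd), ng, nPairs)
    treated <- matrix(mu, ng, nPairs) +
      matrix(subjBase, ng, nPairs, byrow = TRUE) +
      matrix(stats::rnorm(ng * nPairs, sd = noiseSd), ng, nPairs)
    treated[geneNames %in% inducedGenes, ] <-
      treated[geneNames %in% inducedGenes, ] + log2Fold
  })
  expr <- cbind(treated, control)
  rownames(expr) <- geneNames
  colnames(expr) <- c(sprintf("TRT_%02d", seq_len(nPairs)),
                      sprintf("CTL_%02d", seq_len(nPairs)))
  list(expr = expr,
       treated = rep(c(TRUE, FALSE), each = nPairs),
       subject = rep(seq_len(nPairs), 2L),
       truth = list(inducedGenes = inducedGenes, log2Fold = log2Fold,
                    seed = as.integer(seed)))
}

#' Full synthetic suite for target-panel assembly
#'
#' Generates two independent multi-tumor single-cell datasets and one paired
#' activation dataset over a shared gene universe, with the true panel being
#' the planted targets up-regulated in focal-positive myeloid cells AND
#' induced by activation. Extra genes with tumor-only or activation-only
#' evidence are planted so the cross-dataset conjunction is exercised.
#'
#' @param seed Integer seed; the two tumor datasets and the activation
#'   dataset derive distinct sub-seeds from it.
#' @param nTumors,cellsPerTumor,nGenes See
#'   \code{\link{makeSinglecellTumors}}.
#' @param targetGenes True panel genes.
#' @param nTumorOnly,nActivationOnly Number of planted decoy genes with
#'   incomplete evidence.
#' @param nPairs Activation pairs per arm.
#' @return A list with \code{tumorA}, \code{tumorB} (each as
#'   \code{\link{makeSinglecellTumors}}), \code{activation} and
#'   \code{truth$panel}.
#' @export
makePanelSuite <- function(seed = 1L, nTumors = 3L, cellsPerTumor = 500L,
                           nGenes = 1000L,
                           targetGenes = c("IL1B", "CCL7", "CXCL3", "IL1RN",
                                           "INHBA", "IL6", "IL8", "CCL2"),
                           nTumorOnly = 5L, nActivationOnly = 5L,
                           nPairs = 11L) {
  seed <- as.integer(seed)
  tumorOnly <- sprintf("TUMOR_ONLY_%02d", seq_len(nTumorOnly))
  actOnly <- sprintf("ACT_ONLY_%02d", seq_len(nActivationOnly))
  gen <- function(s) {
    makeSinglecellTumors(nTumors, cellsPerTumor, nGenes, seed = s,
                         targetGenes = targetGenes,
                         extraUpGenes = tumorOnly,
                         neutralGenes = actOnly)
  }
  tumorA <- gen(seed * 3L + 1L)
  tumorB <- gen(seed * 3L + 2L)
  activation <- makeActivationPairs(
    nPairs = nPairs, seed = seed * 3L + 3L,
    inducedGenes = c(targetGenes, actOnly),
    geneNames = rownames(tumorA$sce))
  list(tumorA = tumorA, tumorB = tumorB, activation = activation,
       truth = list(panel = sort(targetGenes), tumorOnly = tumorOnly,
                    activationOnly = actOnly, seed = seed))
}
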