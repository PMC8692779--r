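test_that("qcFilter applies both thresholds with inclusive boundaries and is idempotent", {
  nGenes <- 600
  genes <- c(paste0("G", 1:(nGenes - 20)), paste0("MT-", 1:20))
  counts <- matrix(0L, nGenes, 4, dimnames = list(genes, paste0("cell", 1:4)))
  # cell1: 399 detected genes -> removed (below the 400-gene floor)
  counts[1:399, 1] <- 1L
  # cell2: exactly 400 detected genes and exactly 20% mitochondrial -> kept:
  # 396 non-mito genes (one with count 5) = 400 counts, 4 mito genes x 25 = 100
  counts[1:396, 2] <- 1L
  counts[1, 2] <- 5L
  counts[(nGenes - 19):(nGenes - 16), 2] <- 25L
  # cell3: 500 detected but mito fraction 0.25 -> removed
  counts[1:480, 3] <- 1L
  counts[(nGenes - 19):(nGenes - 0), 3] <- 8L
  # cell4: comfortable -> kept
  counts[1:500, 4] <- 2L
  sce <- makeTinySce(counts)
  det <- Matrix::colSums(counts >= 1)
  mitoFrac <- colSums(counts[grepl("^MT-", genes), ]) / colSums(counts)
  expect_equal(unname(det[1:2]), c(399, 400))
  expect_equal(unname(mitoFrac[2]), 0.2)
  expect_equal(unname(mitoFrac[3]), 160 / 640)
  kept <- qcFilter(sce)
  expect_setequal(colnames(kept), c("cell2", "cell4"))
  expect_identical(colnames(qcFilter(kept)), colnames(kept))
})

test_that("positivity is a raw-count >= 1 rule, independent of normalization", {
  counts <- rbind(TREM1 = c(0L, 1L, 5L, 0L), ZERO = 0L,
                  OTHER = c(10L, 0L, 2L, 7L))
  sce <- makeTinySce(counts)
  expect_identical(positivity(sce, "TREM1"), c(FALSE, TRUE, TRUE, FALSE))
  expect_equal(sum(positivity(sce, "ZERO")), 0)
  expect_error(positivity(sce, "ABSENT"), "absent")
  # scaling library sizes does not change positivity (raw counts only)
  counts2 <- counts * 10L
  expect_identical(positivity(makeTinySce(counts2), "TREM1"),
                   positivity(sce, "TREM1"))
})

test_that("normalizeCells scales to the target total and log1p-transforms", {
  counts <- rbind(A = c(2L, 0L), B = c(8L, 10L))
  sce <- makeTinySce(counts)
  norm <- as.matrix(normalizeCells(sce, scale = 100))
  expect_equal(norm["A", 1], log1p(2 / 10 * 100))
  expect_equal(norm["B", 2], log1p(100))
})

test_that("deBetweenGroups detects planted fold changes and composes the core test", {
  gen <- makeSinglecellTumors(nTumors = 1, cellsPerTumor = 750, nGenes = 300,
                              seed = 91, posFracBySubtype = c(TNBC = 0.5))
  sce <- gen$sce
  myel <- sce[, sce$cell_type == "myeloid"]
  grp <- factor(ifelse(positivity(myel, "TREM1"), "pos", "neg"),
                levels = c("pos", "neg"))
  expect_gte(min(table(grp)), 100)
  de <- deBetweenGroups(myel, grp)
  planted <- gen$truth$targetGenes
  expect_true(all(de$significant[de$gene %in% planted]))
  expect_true(all(de$effect[de$gene %in% planted] > 0))
  # per-gene statistic equals the core wilcoxon on extracted vectors
  lognorm <- as.matrix(normalizeCells(myel))
  g <- planted[1]
  expect_equal(de$p[de$gene == g],
               wilcoxonRankSum(lognorm[g, grp == "pos"],
                               lognorm[g, grp == "neg"])$p)
  expect_error(deBetweenGroups(myel, rep("one", ncol(myel))), "2 groups")
})

test_that("label permutations of one population yield no significant genes", {
  gen <- makeSinglecellTumors(nTumors = 1, cellsPerTumor = 400, nGenes = 200,
                              seed = 93, posFracBySubtype = c(TNBC = 0.4))
  myel <- gen$sce[, gen$sce$cell_type == "myeloid"]
  clean <- vapply(1:10, function(s) {
    grp <- withr::with_seed(1000 + s,
      factor(sample(rep(c("a", "b"), length.out = ncol(myel)))))
    sum(deBetweenGroups(myel, grp)$significant)
  }, 1L)
  expect_gte(sum(clean == 0L), 9)
})

test_that("markerGroupCompare separates a marker-coupled target", {
  gen <- makeSinglecellTumors(nTumors = 1, cellsPerTumor = 600, nGenes = 250,
                              seed = 95, posFracBySubtype = c(TNBC = 0.4))
  myel <- gen$sce[, gen$sce$cell_type == "myeloid"]
  res <- markerGroupCompare(myel, "TREM1", gen$truth$targetGenes[1])
  expect_lt(res$p, 0.001)
  expect_equal(res$nPositive, sum(positivity(myel, "TREM1")))
  expect_equal(res$nNegative, ncol(myel) - res$nPositive)
  expect_error(markerGroupCompare(myel, "TREM1", "ABSENT"), "absent")
})

test_that("assemblePanel takes the three-way conjunction of up-regulated genes", {
  genes <- c(panelGeneNames, paste0("BG", 1:12))
  deA <- deStub(genes, sigUp = c(panelGeneNames, "BG1", "BG3"))
  deB <- deStub(genes, sigUp = c(panelGeneNames, "BG2", "BG3"))
  deAct <- deStub(genes, sigUp = c(panelGeneNames, "BG4"), sigDown = "BG3")
  pan <- assemblePanel(deA, deB, deAct)
  expect_identical(panelGenes(pan), sort(panelGeneNames))
  ev <- panelEvidence(pan)
  expect_identical(ev$gene[ev$member], sort(panelGeneNames))
  # BG3 is up in both tumors but DOWN in activation: excluded
  expect_false("BG3" %in% panelGenes(pan))
  # order invariance and tumor-table symmetry
  shuf <- withr::with_seed(4, sample(length(genes)))
  expect_identical(panelGenes(assemblePanel(deA[shuf, ], deB, deAct)),
                   panelGenes(pan))
  expect_identical(panelGenes(assemblePanel(deB, deA, deAct)),
                   panelGenes(pan))
  # disjoint significant sets -> empty panel
  empty <- assemblePanel(deStub(genes, "BG1"), deStub(genes, "BG2"),
                         deStub(genes, "BG4"))
  expect_length(panelGenes(empty), 0)
  expect_error(assemblePanel(deA, deStub(paste0("X", 1:3), "X1"), deAct),
               "no shared genes")
})

test_that("tumorProfile ranks tumors by myeloid positivity with per-compartment panel means", {
  counts <- rbind(TREM1 = c(0L, 0L, 0L, 2L, 1L, 0L),
                  IL1B = c(1L, 2L, 1L, 9L, 8L, 1L),
                  OTHER = 3L)
  sce <- makeTinySce(counts,
                     tumor_id = rep(c("T01", "T02"), each = 3),
                     cell_type = rep(c("myeloid", "myeloid", "cancer"), 2),
                     subtype = rep(c("ER+", "TNBC"), each = 3))
  prof <- tumorProfile(sce, "IL1B")
  expect_identical(prof$tumor_id, c("T02", "T01"))
  expect_equal(prof$pct_positive, c(100, 0))
  expect_false(any(prof$flagged))
  # tumor with no myeloid cells is flagged with undefined frequency
  sce2 <- makeTinySce(counts, tumor_id = rep(c("T01", "T02"), each = 3),
                      cell_type = c(rep("myeloid", 3), rep("cancer", 3)))
  prof2 <- tumorProfile(sce2, "IL1B")
  expect_true(prof2$flagged[prof2$tumor_id == "T02"])
  expect_true(is.na(prof2$pct_positive[prof2$tumor_id == "T02"]))
})

test_that("a planted positivity gradient couples frequency and myeloid panel expression", {
  fracs <- seq(0.10, 0.65, length.out = 12)
  names(fracs) <- paste0("ST", 1:12)
  gen <- makeSinglecellTumors(nTumors = 12, cellsPerTumor = 250, nGenes = 200,
                              seed = 97, subtypes = names(fracs),
                              posFracBySubtype = fracs)
  prof <- tumorProfile(gen$sce, gen$truth$targetGenes)
  expect_identical(sort(prof$tumor_id), sort(unique(gen$sce$tumor_id)))
  expect_true(!is.unsorted(rev(prof$pct_positive)))
  # the planted gradient couples frequency and myeloid panel expression;
  # binomial sampling of positive cells permits at most adjacent-rank swaps
  rho <- rankCorr(prof$pct_positive, prof$panel_mean_myeloid)$rho
  expect_gte(rho, 0.95)
})

test_that("subtypeFrequencyTest composes Kruskal-Wallis over per-tumor frequencies", {
  prof <- data.frame(subtype = rep(c("TNBC", "ER+", "HER2+"), each = 10),
                     pct_positive = c(seq(40, 58, 2), seq(10, 28, 2),
                                      seq(24, 42, 2)))
  res <- subtypeFrequencyTest(prof)
  expect_equal(res$H,
               kruskalWallis(split(prof$pct_positive, prof$subtype))$H)
  expect_lt(res$p, 0.05)
  expect_equal(nrow(res$pairwise), 3)
  # subtype with a single tumor is excluded with a warning
  prof2 <- rbind(prof, data.frame(subtype = "RARE", pct_positive = 33))
  expect_warning(res2 <- subtypeFrequencyTest(prof2), "RARE")
  expect_false("RARE" %in% names(res2$groups))
})

test_that("a planted subtype gradient is detected at 10 tumors per group", {
  gen <- makeSinglecellTumors(nTumors = 30, cellsPerTumor = 120, nGenes = 150,
                              seed = 99,
                              subtypes = c("TNBC", "ER+", "HER2+"),
                              posFracBySubtype = c("TNBC" = 0.5, "ER+" = 0.15,
                                                   "HER2+" = 0.3))
  prof <- tumorProfile(gen$sce, gen$truth$targetGenes)
  res <- subtypeFrequencyTest(prof)
  expect_lt(res$p, 0.05)
  tn <- res$pairwise[res$pairwise$group1 == "ER+" & res$pairwise$group2 == "TNBC", ]
  expect_lt(tn$p, 0.05)
})
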