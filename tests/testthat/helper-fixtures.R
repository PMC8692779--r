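# Small programmatic fixtures shared across test files.

# tiny SingleCellExperiment from a dense count matrix and cell metadata
makeTinySce <- function(counts, tumor_id = "T01", cell_type = "myeloid",
                        subtype = "TNBC") {
  nc <- ncol(counts)
  if (is.null(colnames(counts))) colnames(counts) <- sprintf("C%03d", seq_len(nc))
  cd <- S4Vectors::DataFrame(
    tumor_id = rep_len(tumor_id, nc),
    cell_type = rep_len(cell_type, nc),
    subtype = rep_len(subtype, nc),
    row.names = colnames(counts))
  sce <- SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = methods::as(counts, "CsparseMatrix")),
    colData = cd)
  SummarizedExperiment::rowData(sce)$mito <- grepl("^MT-", rownames(sce))
  sce
}

# DE-table stub for assemblePanel tests
deStub <- function(genes, sigUp, sigDown = character(0)) {
  data.frame(gene = genes,
             effect = ifelse(genes %in% sigUp, 2,
                      ifelse(genes %in% sigDown, -2, 0.1)),
             p = ifelse(genes %in% c(sigUp, sigDown), 1e-6, 0.5),
             p_adj = ifelse(genes %in% c(sigUp, sigDown), 1e-5, 0.8),
             significant = genes %in% c(sigUp, sigDown))
}

panelGeneNames <- c("IL1B", "CCL7", "CXCL3", "IL1RN", "INHBA", "IL6",
                    "IL8", "CCL2")
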