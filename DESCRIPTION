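Package: tremscreen
Title: Immune Subclass Classification and Myeloid Antagonist Screening in
    Tumor Transcriptomics
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Classifies tumors into immune subclasses (FID/WID/PID) from
    effector immune gene-signature scores by a population-tertile rule, runs a
    genome-wide logistic-regression screen for genes whose high expression
    antagonizes immune-associated chemotherapy response (ranked by the signed
    Wald Z of the gene-by-subclass interaction), performs distant
    metastasis-free survival analyses (expression-quartile Kaplan-Meier,
    univariable and multivariable Cox models, split-cohort per-gene survival
    screens, stratified analyses against externally estimated immune cell
    fractions), and assembles a cross-dataset TREM-1 target gene panel from
    single-cell tumor profiles and monocyte activation experiments. Ships a
    synthetic-cohort generator with planted ground truth so the whole pipeline
    is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    S4Vectors,
    SummarizedExperiment,
    SingleCellExperiment,
    survival,
    withr,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
biocViews: Transcriptomics, GeneExpression, SingleCell, Survival,
    Classification, ImmunoOncology
RoxygenNote: 7.3.3
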