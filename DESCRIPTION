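Package: pathwayPRS
Title: Pathway-Specific Polygenic Risk Scores for Blood Pressure Traits
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Construction and evaluation of pathway-restricted polygenic
    risk scores (PRS) for blood pressure traits using the
    clumping-and-thresholding method. Provides a synthetic three-cohort
    study generator with LD-block genotype structure and a known additive
    phenotype model, per-SNP additive association scans with covariate
    adjustment, EM-based maximum-likelihood haplotype frequency estimation
    for pairwise LD r-squared, greedy p-value-ordered clumping, SNP-to-gene-set
    mapping, dosage-based PRS scoring, validation-cohort threshold selection,
    and target-cohort evaluation (incremental R-squared, decile
    stratification, two-sample t-tests with Cohen's d, and rank-based AUC
    for hypertension status).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    withr,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    VariantAnnotation,
    rtracklayer,
    fgsea
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: GenomeWideAssociationStudy, SNP, StatisticalMethod, Genetics
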