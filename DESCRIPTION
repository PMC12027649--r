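Package: methrisk
Title: Methylation Risk Scores from Mixed-Model Omic Association and BLUP
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds and evaluates methylation risk scores (MRS) for binary
    traits from post-QC DNA methylation beta matrices and genotype dosages.
    Provides omics and genomic relationship matrices, multi-component
    average-information REML variance partitioning on the observed scale,
    mixed-linear-model per-probe association scans (single-component and
    multi-component with distance-based target exclusion), BLUP probe
    effects, threshold-based probe selection, MRS and polygenic-score
    computation, logistic-model evaluation with DeLong confidence intervals,
    and a leave-one-institution-out cross-validation pipeline. A synthetic
    cohort generator with recorded ground truth supports recovery testing of
    every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    vcfR,
    yaml,
    optparse
Config/testthat/edition: 3
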