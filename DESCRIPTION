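Package: cardiofate
Title: Transcriptomic Determinants of iPSC Cardiac Differentiation Fate
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Links induced pluripotent stem cell (iPSC) transcriptomes to the
    outcome of directed cardiac differentiation. Provides cell-population
    deconvolution of bulk RNA-seq against single-cell derived signatures via
    constrained least squares, a cardiomyocyte/epicardium (CM/EPDC) fate
    threshold sweep with a label-permutation null, Storey q-value false
    discovery control, per-gene and L1-penalised joint models of the variance
    in fate explained by signature genes, X-chromosome allelic-imbalance
    analysis with pseudoautosomal masking, gene-set enrichment on the fate
    contrast, covariate and genotype association scans, cross-cohort
    replication statistics, and a synthetic-cohort generator that plants
    known fractions, signature effects, X-inactivation states and genetic
    effects so every stage is testable without access to restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    glmnet,
    matrixStats,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
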