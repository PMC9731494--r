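Package: proteoclust
Title: Serum Proteomics Endotype Discovery and Cross-Cohort Validation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An end-to-end pipeline for aptamer-based (SOMAscan-style) serum
    proteomics endotyping: four-step intensity standardization
    (hybridization normalization, plate scaling, median signal
    normalization, calibration) followed by log2 transformation,
    unsupervised two-cluster patient stratification on the most variable
    proteins, empirical-Bayes moderated differential expression with
    fold-change and FDR significance calls, a median-based per-patient
    protein score, hypergeometric set over-representation, a deterministic
    biomarker signature selection procedure, cluster-versus-clinical
    association statistics, and agnostic re-clustering for cross-cohort
    transfer validation and paired-visit cluster-switching analysis. A
    synthetic cohort generator with planted cluster structure makes every
    stage testable without external data.
License: MIT
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
    limma,
    mclust,
    withr
Config/testthat/edition: 3
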