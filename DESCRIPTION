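Package: cnvclim
Title: Copy Number Variation and Climate Association Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for landscape-genomic analysis of copy number
    variation (CNV). Provides quality control of PennCNV-style CNV call tables,
    merging of calls into copy number variable regions (CNVRs), estimation of
    annual solar radiation from sunshine fraction and latitude, genotype-
    environment association scans (univariate logistic regression with Wald
    statistics and a latent factor mixed model with genomic-control
    calibration), probe-based CNV association with solar radiation under a
    Balding-Nichols kinship mixed model with max(T) permutation correction,
    and gene/QTL interval annotation. A synthetic-data generator emulating a
    multi-site, climatically structured sampling design makes every stage
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils,
    methods,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
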