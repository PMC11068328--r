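Package: repquant
Title: Somatic Repeat Instability Quantification from Fragment Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-style toolkit for quantifying somatic CAG-repeat
    instability and its downstream phenotypes in knock-in mouse models of
    Huntington's disease. Reads GeneMapper-style fragment-analysis peak tables
    (and raw ABIF traces), computes peak-height-weighted instability,
    expansion and contraction indices against an ear-biopsy reference, runs
    cohort-level multivariate statistics (PCA of repeat-profile summary
    statistics and ANCOVA with the ear covariate), classifies per-gene
    transcriptional rescue from differential-expression contrasts via the
    alpha-multiplier, quantifies aggregate immunostaining by intensity
    thresholding with pixel-size gates, and ships seeded synthetic-data
    generators with planted ground truth for every input the pipeline
    consumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
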