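Package: refstab
Title: Reference-Gene Stability Ranking and Efficiency-Corrected qPCR Quantification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for choosing stable reference (housekeeping) genes for
    quantitative RT-PCR normalization and for validating that choice. Implements
    the comparative pairwise delta-Ct stability statistic, the geNorm expression
    stability measure M with stepwise exclusion and pairwise-variation ratios
    V(n/n+1), amplification-curve baseline correction with window-of-linearity
    efficiency estimation and amplicon-group Ct extraction, and efficiency-
    corrected (Pfaffl-type) relative quantification of target genes against one
    or more reference genes. Includes a synthetic-data generator with known
    ground truth for Ct matrices and amplification curves, condition-stratified
    ranking reports with reference-pair recommendations, broom-style tidiers and
    ggplot2 autoplot methods.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    readxl,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
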