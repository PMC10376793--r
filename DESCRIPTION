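Package: pharmacoscreen
Title: Subtype-Stratified Drug-Gene Correlation Screening for Cancer
    Cell Line Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Screens for genes whose basal expression correlates with drug
    sensitivity or resistance across cancer cell line panels, stratified by
    tissue subtype and aggregated by drug target-pathway category. Pearson
    correlations between log2 expression and area-under-dose-response-curve
    (AUC) values are computed per (gene, drug, subtype) group, stabilised by
    Fisher's z-transformation scaled by sqrt(n - 3), and thresholded against
    a fixed or permutation-calibrated cutoff. Significant correlations are
    aggregated into per-category global scores (percent of significant
    drug-subtype tests, separately for sensitivity and resistance), called
    against a genome-wide quantile cutoff, and decomposed into per-subtype
    contributions. Includes hierarchical clustering of score matrices,
    ggplot2 report figures, and a synthetic-data generator that plants
    gene-drug-subtype correlations of known sign and magnitude for
    end-to-end validation without external downloads.
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
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
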