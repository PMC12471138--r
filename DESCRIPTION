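Package: fundustex
Title: Vascular Texture and Color Distribution Analysis of Retinal Fundus
    Images
Version: 0.1.0
Authors@R:
    person("fundustex", "developers", email = "dev@fundustex.org",
           role = c("aut", "cre"))
Description: Dual-framework analysis of color retinal fundus photographs:
    matched-filter segmentation of the retinal vasculature followed by
    gray-level co-occurrence matrix (Haralick) texture profiling, and global
    RGB color-distribution analysis (per-channel and bivariate histograms,
    Mahalanobis group separability). Includes a seeded synthetic fundus
    cohort generator with ground-truth vessel masks so that the full
    pipeline, including its statistical comparison layer (two-sample
    Kolmogorov-Smirnov, Wilcoxon-Mann-Whitney, Lilliefors), is testable
    without any image download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    png,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
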