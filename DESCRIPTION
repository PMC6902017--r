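Package: ibi
Title: Identification of Biomarker Genes in Individual Samples
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Identifies biomarker genes of individual samples from a gene
    expression matrix. Each sample is regressed against the average
    expression profile of its own group by ordinary least squares; the
    per-gene residuals are smoothed with a Gaussian kernel density
    estimator and genes whose residuals fall in either tail of the
    smoothed cumulative distribution are called as sample-specific
    biomarkers. Includes a Welch t-test differential-expression filter
    to define the gene universe, rank-matrix Kolmogorov-Smirnov
    specificity testing, biomarker frequency analysis across groups,
    a seeded synthetic expression simulator with grouped perturbations,
    and recovery scoring against simulation ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
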