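Package: markerdens
Title: Density-Based Stratification of Multiplex Imaging Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Threshold-free comparison of subjects in multiplex tissue-imaging
    cohorts by the probability density of a functional marker across cells of
    the tumor microenvironment. Per-subject Gaussian kernel density estimates
    on a common grid are compared with pairwise Jensen-Shannon distances; the
    distance matrix drives hierarchical patient stratification or, through its
    similarity transform exp(-D), variance-component association tests against
    continuous and right-censored survival outcomes. Includes the classical
    two-threshold positivity comparator, quantile-vector K-means, Monte-Carlo
    simulation designs for benchmarking clustering accuracy, and a small
    command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    survival,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse
Config/testthat/edition: 3
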