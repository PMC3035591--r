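Package: ntindex
Title: Normalized Tree Index for Correlating Cluster Trees with Nominal Labels
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the correlation between a hierarchical clustering of
    high-dimensional data (for example microarray expression profiles) and a
    nominal label such as a clinical parameter. Every split of the cluster
    tree is scored by the negative log probability of its observed class
    distribution under the multivariate hypergeometric model; the Tree Index
    (TI) is the standard deviation of these splitting scores. Monte-Carlo
    estimates of the index floor (permuted labels on the fixed tree) and
    ceiling (class-pure ordered trees) normalize the TI to the Normalized
    Tree Index (NTI) in [0, 1], and the same permutation draws yield an
    empirical p-value. Includes the full screening pipeline from a log-ratio
    matrix to a per-parameter report: scaling to [-1, 1], average-linkage
    clustering under a correlation distance, rule-based binning of ordinal
    and interval clinical columns, and a synthetic-data generator with
    planted class structure for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    Rcpp,
    rlang,
    stats,
    tibble,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    phangorn,
    readr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
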