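Package: morphnet
Title: Individual Morphological Brain Networks from Regional Gray-Matter
    Distributions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds individual (single-subject) morphological brain networks
    from regional gray-matter-volume distributions. Regional voxel samples are
    turned into kernel-density-estimated probability distributions on a shared
    grid, pairwise Jensen-Shannon and symmetric Kullback-Leibler divergences
    define similarity edge weights between atlas regions, and the resulting
    weighted networks are swept over a sparsity range to yield binary-graph
    topology curves (clustering, path length, small-world indices, global and
    nodal efficiencies, centralities) summarised by area under the curve.
    Includes a synthetic cohort generator emulating a two-group case-control
    design, and the group-level statistical battery: normality-gated two-sample
    tests, chi-square tests, covariate-adjusted linear models,
    Benjamini-Hochberg false-discovery-rate correction over nodal metrics, and
    covariate-adjusted partial correlations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    igraph,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    RNifti,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
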