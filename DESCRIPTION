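Package: inflectr
Title: Data-Driven Selection of Metacluster Numbers for Cytometry Clustering
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Selects an optimal number of metaclusters for high-dimensional
    cytometry data by deliberate overclustering with a self-organizing map,
    metaclustering the SOM nodes over a schedule of target counts
    (agglomerative Ward or Monti-style consensus clustering), scoring every
    endpoint by the fraction of per-metacluster marker distributions that are
    unimodal (Hartigan dip test) and narrow (interquartile-range check), and
    locating the knee of the resulting unimodality-versus-cluster-count curve
    with the Salvador-Chan L-method, optionally on a fitted four-parameter
    logistic curve. Includes readers for FCS and delimited event tables, the
    arcsinh transform, a synthetic mixture generator for validation, and
    diagnostic plots.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    parallel,
    tools,
    minpack.lm,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2,
    optparse
Config/testthat/edition: 3
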