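Package: hypercoop
Title: Evolutionary Games and Metric Clusters on Hyperbolic Scale-Free Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation toolkit for evolutionary game dynamics on scale-free
    networks with a latent hyperbolic geometry. Generates temperature-controlled
    hyperbolic random graphs with tunable degree heterogeneity and mean local
    clustering, runs synchronous Fermi-rule imitation dynamics for 2x2 social
    dilemmas on their giant component, constructs initial cooperator
    configurations (random, degree-preferential, metric clusters, multiple
    metric clusters, connected clusters), and quantifies the spatial
    self-organization of cooperators in the angular similarity dimension via a
    Kolmogorov-Smirnov clustering statistic, binned angular cooperation
    profiles, and intercluster-link fractions. Includes orchestration for
    game-parameter phase diagrams, heterogeneity/clustering sweeps, and
    cluster-size scaling experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    Rcpp,
    stats,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
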