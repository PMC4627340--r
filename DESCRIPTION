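Package: prognet
Title: Network-Module Prognostic Signatures for Basal-Like Breast Cancer
Version: 0.1.0
Authors@R: person("Robin", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Discovery and evaluation of prognostic gene-network modules in
    basal-like breast cancer cohorts. Implements univariate Cox
    proportional-hazards feature selection, correlation-weighted functional
    network construction, Markov clustering (MCL) of the weighted network,
    module-index and combination-index scoring based on geometric means of
    log2 expression, Kaplan-Meier/log-rank survival stratification,
    nearest-centroid molecular subtyping, hypergeometric pathway
    over-representation, and a three-marker Allred immunohistochemistry
    composite risk score. A synthetic-cohort generator with planted
    prognostic modules makes the full pipeline testable without external
    data downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    survival,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
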