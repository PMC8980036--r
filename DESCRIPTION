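Package: gatedbn
Title: Optimal Bayesian Networks of Binary Driver Events with Fisher
    Annotation and Logic-Gate Fitting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Learns globally optimal Bayesian network structures from
    binary sample-by-event matrices, such as cancer cohort driver-event
    tables, using a decomposable BDeu (or BIC) score combined with an
    integer edge-penalty structure prior. Structure search is an exact
    dynamic program over variable subsets, so the returned network
    maximises the penalised score. Learned networks are decomposed into
    families (a child and its parents) for heatmap visualisation,
    annotated with pairwise Fisher exact test statistics
    (Benjamini-Hochberg corrected), and optionally summarised by the
    best-fitting boolean logic gate (AND/OR/XOR, optional NOT) per
    family. Includes a forward sampler for discrete Bayesian networks
    and a packaged five-node example network for end-to-end simulation
    studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    jsonlite,
    igraph
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
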