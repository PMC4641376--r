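Package: ieatools
Title: Integrative Enrichment Analysis of Differential Expression and
    Expression Variance
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Pathway dysregulation analysis for heterogeneous case/control
    expression studies.  Genes are classified as differentially expressed
    (DEG) or differentially variable (DEVG, via a rank-sum test on absolute
    deviations), pathways are scored with a joint two-category
    hypergeometric tail test (HT2) that accounts for both gene classes at
    once, pathway crosstalks are mapped with a two-way random walk with
    restart on a (differential) interaction network, and pathway-level
    subtype-factors are screened against clinical indices by
    supervised-like clustering of binarized DEVG expression.  A synthetic
    data generator with planted effects supports calibration and power
    evaluation of every step.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    stats,
    utils,
    graphics,
    grDevices,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
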