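Package: sppmine
Title: Safe Pattern Pruning for Predictive Pattern Mining
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Sparse elastic-net linear models whose features are the
    sub-structures (itemsets, subsequences, labeled subgraphs) of structured
    inputs.  The exponential feature space is never materialized: GAP safe
    screening is lifted to a monotone tree-pruning rule (safe pattern
    pruning), so whole subtrees of the pattern enumeration tree are provably
    eliminated before optimization.  Includes single- and two-reference
    screening with the closed-form sphere-intersection bound, dynamic
    screening during coordinate descent, one- and two-dimensional
    regularization paths, cross-validation with full-data reference
    solutions, a planted-pattern synthetic data generator, and a
    full-enumeration proximal-gradient oracle for verification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    Biostrings,
    glmnet,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
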