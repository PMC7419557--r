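Package: conetdiff
Title: Cross-Cohort Microbial Co-Abundance Network Comparison
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers microbial co-abundance and co-occurrence networks from
    compositional metagenomic abundance tables (MetaPhlAn-style species tables,
    HUMAnN2-style pathway tables) separately per cohort, using SparCC basis
    correlations with permutation false-discovery control intersected with a
    conditional-independence sparsifier (lasso neighborhood selection with StARS
    stability selection on centered log-ratio data). Edges are then compared
    between cohorts with Cochran-Q heterogeneity tests under cohort-label
    permutation FDR, cohort-specific edges are called with an interquartile-range
    outlier rule, key (hub) species and pathways are detected against
    permutation-calibrated cutoffs, and calls are adjusted for host covariates
    via partial correlation. A logistic-normal-multinomial simulator with a known
    sparse basis correlation network, planted cohort-specific edges, zero
    inflation and covariate confounding provides ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    glmnet,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    metafor
Config/testthat/edition: 3
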