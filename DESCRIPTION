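Package: symptomnet
Title: Ising Network Analysis of Binary Psychiatric Symptom Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Estimates weighted, undirected networks over binary psychiatric
    symptoms by nodewise l1-penalized logistic regression with extended-BIC
    neighborhood selection (the eLasso scheme), and summarizes the result as
    within- and between-diagnosis connectivity tables, graph descriptives
    (clustering coefficient, average shortest path length, degrees), and a
    force-directed figure. Includes a block-structured Ising simulator with
    screener skip-logic, zero-imputation of skipped items, and missingness
    filtering, so that every stage of the pipeline can be exercised and
    validated without access to restricted survey data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    glmnet,
    igraph,
    jsonlite,
    yaml,
    Rcpp,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
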