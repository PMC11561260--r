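Package: fatebias
Title: Quantifying Cell Plasticity from Single-Cell Type Probabilities
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies cell plasticity from single-cell expression data as
    the proportion of hybrid cells (P_hc) along fate-pair transitions. A
    probabilistic cell-type classifier trained on a reference-annotated
    expression matrix yields per-cell class probabilities; for an ordered
    fate pair (A, B) each cell's fate bias Prob.A/(Prob.A + Prob.B) is
    computed and P_hc is the fraction of eligible cells whose bias falls in
    a hybrid window such as [0.4, 0.6]. Includes ECDF ambiguity curves,
    reference-versus-prediction overlap matrices, in-silico gene-set
    knockouts with re-prediction and partial-reversal calls, and a
    negative-binomial branching-differentiation simulator with known
    per-cell fate mixtures for validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    glmnet,
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    readr,
    generics,
    jsonlite,
    yaml,
    withr,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
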