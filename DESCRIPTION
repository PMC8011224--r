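Package: sexlabelr
Title: Expression-Based Sex Labeling, Misannotation Detection, and
    Sex-Bias Summaries for Public Transcriptomics
Version: 0.1.0
Authors@R:
    person("Maintainer", "sexlabelr", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Infers sample sex from X/Y-chromosome gene expression with a
    penalized logistic regression model selected by study-stratified nested
    cross-validation, flags metadata sex misannotations per study with
    Gaussian-mixture clustering of sample sex scores, normalizes metadata
    mentions of cell lines and drugs against reference lexicons, and computes
    sex-bias summaries (study sex categories, cell-line sex switching,
    ATC-class enrichment). A synthetic-data module emulates the statistical
    structure of large public expression compendia so every stage is testable
    without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    glmnet,
    igraph,
    jsonlite,
    Matrix,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
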