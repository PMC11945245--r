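Package: pvic
Title: Disproportionality Analysis of Spontaneous Adverse-Event Reports with
    the Bayesian Information Component
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A pipeline for pharmacovigilance signal detection on
    VigiBase-style relational extracts of individual case safety reports:
    ingestion of the raw report tables with dictionary joins, exclusion of
    suspected duplicates and reports with unknown demographics, mapping of
    reports to named drug (substance) sets and adverse-reaction term sets,
    construction of 2x2 contingency tables with margins, the BCPNN
    information component with its variance and 95% credibility interval,
    tri-state signal classification, and covariate-adjusted logistic
    regression of event reporting. Includes a synthetic report generator
    with planted ground truth so every stage is testable without access to
    the restricted source database.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
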