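Package: mrbnbench
Title: Simulation Benchmarking of Mendelian Randomization and Bayesian
    Network Causal Discovery
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation pipeline comparing summary-statistic Mendelian
    randomization estimators (inverse-variance weighted, MR-Egger,
    MR-PRESSO), with and without conditional-independence ("UniqueIV")
    instrument filtering, against a four-variable bootstrap-averaged
    Bayesian network procedure for detecting causal relationships
    between continuous traits. Includes a synthetic-data generator for
    random causal trait networks with binary instrumental variables and
    controlled horizontal pleiotropy, and evaluation utilities for
    empirical false discovery rate, power, discovery counts and ROC
    curves across replicates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    ggplot2,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
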