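Package: lncdcs
Title: Predicting lncRNA-Disease Associations from a Tripartite
    Disease-miRNA-lncRNA Network
Version: 0.1.0
Authors@R:
    person("lncdcs", "maintainers", email = "lncdcs@example.org",
           role = c("aut", "cre"))
Description: Scores candidate long noncoding RNA (lncRNA) to disease
    associations without using any known lncRNA-disease links.  Two
    bipartite association tables (disease-miRNA and miRNA-lncRNA) are
    merged over their shared miRNAs into a tripartite network; a
    radius-capped shortest-path matrix is turned into distance
    correlation coefficients, node-pair association degrees, and a
    disease-by-lncRNA prediction block, which is optionally weighted by
    miRNA-based functional similarity matrices of diseases and lncRNAs.
    Includes a leave-one-out ROC/AUC evaluation harness, a synthetic
    network generator with a plantable signal, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    optparse,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
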