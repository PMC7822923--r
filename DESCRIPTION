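Package: gldnet
Title: Multiomic Coexpression and Causal Network Analysis of Glucose and
    Lipid Regulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A pipeline for discovering and dissecting gene coexpression
    modules that link lipid and glucose metabolism in liver transcriptomes.
    Starting from raw read counts, the package filters and TMM-normalizes
    expression, removes batch (flow-cell) effects and principal-component
    outliers, builds weighted coexpression modules and correlates their
    eigengenes with clinical traits, maps cis-eQTLs, runs a causal inference
    test on SNP-gene-metabolite trios, learns consensus Bayesian causal
    networks by MCMC with eQTL structure priors, and ranks key driver genes
    across networks with a weighted composite score. A synthetic multiomic
    cohort generator with known causal ground truth (a planted glucose- and
    lipid-determining module and master regulator) makes every stage
    testable without access to controlled human data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    edgeR,
    igraph,
    jsonlite,
    Rcpp,
    stats,
    utils,
    vcfR
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
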