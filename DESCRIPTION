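Package: dispersim
Title: Simulation and Detection of Differential Expression Dispersion in
    RNA-Seq Count Data
Version: 0.1.0
Authors@R:
    person("dispersim", "developers", email = "dispersim@example.org",
           role = c("aut", "cre"))
Description: Tools to study differences in gene expression dispersion (the
    negative binomial overdispersion parameter) between two biological
    conditions in bulk RNA-seq data. Provides a negative binomial count
    simulator with controlled mean and dispersion fold changes, four
    differential-dispersion detectors (Levene's test on log counts, a
    mean/variance reparameterized negative binomial Wald test, a robust
    M-estimation test with Tukey biweight downweighting, and a double
    negative binomial regression likelihood-ratio test),
    Benjamini-Hochberg and Benjamini-Yekutieli multiple-testing
    adjustment, an FDR/TPR/AUC evaluation harness, a sign-validation
    consensus workflow for calling overdispersed genes among
    non-differentially-expressed genes, and a Gene Ontology enrichment
    module with semantic-similarity redundancy reduction.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    edgeR,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
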