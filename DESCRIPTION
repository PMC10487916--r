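Package: mircna
Title: Integrated Copy-Number and miRNA Expression Analysis for Triple-Negative Breast Cancer
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An integrated analysis pipeline for triple-negative breast cancer
    (TNBC) combining array-CGH copy-number profiles with NanoString-style miRNA
    expression. Implements probe-run aberration calling (>= 3 consecutive probes
    beyond a log2-ratio threshold), cytoband penetrance aggregation and recurrent
    region selection, control-based count normalization with t-test/BH-FDR
    differential expression and correlation-based hierarchical clustering,
    two-stage CNA-miRNA integration (direction concordance and 2-of-3 consensus
    target intersection), and downstream validation statistics (delta-delta-Ct
    relative quantification with Ct exclusion rules, ROC/AUC with bootstrap
    confidence intervals, dichotomized clinical associations with a multivariate
    option, and Kaplan-Meier/log-rank survival on a median split). A synthetic
    data module generates every pipeline input with known implanted truth so all
    stages are testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    ape,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    jsonlite
Config/testthat/edition: 3
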