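Package: codc
Title: Copula-Based Detection of Differential Coexpression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Detects differential coexpression of gene pairs between two
    phenotype conditions (e.g. matched normal and tumor samples) by modeling
    each pair's joint expression distribution with an empirical copula and
    scoring the change as the two-sample Kolmogorov-Smirnov distance between
    the per-condition copulas. Because the score is built on ranks it is
    invariant to strictly increasing per-gene transforms and robust to noise.
    Includes RNA-seq count preprocessing (low-expression filtering,
    median-of-totals normalization, dispersion-based variable-gene selection),
    differentially coexpressed module detection by average-linkage clustering
    of the copula distance, module eigengene summaries and eigengene
    correlation networks, gene-set over-representation scoring of modules, a
    beta-kernel copula density diagnostic, and a simulation toolkit with
    exact-correlation generators, noise injection, and the concordance,
    stability and recovery experiments used to validate the method.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    MASS,
    data.table,
    fgsea,
    stats,
    utils
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
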