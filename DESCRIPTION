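Package: protmr
Title: Proteome-Wide Two-Sample Mendelian Randomisation with
    Colocalisation Follow-Up
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for proteome-wide two-sample Mendelian randomisation
    from GWAS summary statistics: dual-study cis-pQTL instrument selection
    (genome-wide significance union, ambiguous-palindrome removal,
    cross-study replication with a pairwise heterogeneity z-test, cis/trans
    classification, best-source selection, LD clumping, MHC and
    multi-aptamer exclusion), exposure-outcome harmonisation with proxy
    substitution, a suite of MR estimators (Wald ratio, inverse-variance
    weighted, MR-Egger, weighted median, simple and weighted mode) with
    Cochran's Q heterogeneity diagnostics, Bonferroni gating, and Bayesian
    colocalisation via Wakefield approximate Bayes factors, including
    SuSiE fine-mapping of summary statistics for multi-signal regions.
    Includes a synthetic GWAS generator with block-AR(1) linkage
    disequilibrium and known causal architecture so that the whole pipeline
    is testable end-to-end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
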