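Package: mircq
Title: Censored-Normal Analysis of Serum miRNA RT-qPCR Cq Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quality control, reference-miRNA selection and differential
    expression for high-throughput RT-qPCR panels in which non-detects are
    right-censored at the instrument detection limit (Cq = 40). Implements
    censored-normal maximum likelihood, truncated-normal imputation of
    non-detects, four reference-gene stability algorithms (geNorm, NormFinder,
    BestKeeper, comparative delta-Ct) with consensus rank aggregation and TOST
    equivalence screening, two-group tobit regression with 2^-ddCt fold
    changes, and hypergeometric over-representation analysis of miRNA target
    genes. Includes a synthetic-cohort generator with planted ground truth
    for method validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    fgsea,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    survival,
    withr,
    optparse
Config/testthat/edition: 3
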