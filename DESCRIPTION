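Package: cfdrtriage
Title: Pedigree Cluster Statistics and Cost Modelling for Hereditary
    Colorectal Cancer Triage
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes the cluster-of-first-degree-relatives (CFDR) tumor
    count and lowest age at diagnosis (LAD) from pedigrees, applies triage
    criteria that select probands for direct multi-gene panel mutation
    screening versus stepwise mismatch-repair (MMR) functional testing for
    suspected Lynch syndrome, and compares laboratory costs of the two
    diagnostic strategies. Includes a synthetic referral-cohort generator
    with autosomal-dominant Lynch carriers, gene-specific onset models and
    a sporadic MLH1-methylation background, plus Mann-Whitney U cohort
    comparisons and report exports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
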