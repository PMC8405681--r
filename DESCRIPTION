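Package: coexrank
Title: Guide-Gene Co-Expression Ranking and Permutation-Based Gene-Set
    Enrichment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Identifies gene networks co-regulated with a single guide
    transcript in bulk transcriptome cohorts. Correlates the guide gene
    with every other expressed gene within metadata-defined sample strata,
    converts the correlation vector into a centred and scaled pre-ranked
    statistic, and tests pathway collections (GMT) for enrichment or
    depletion with a weighted running-sum enrichment score, a
    gene-permutation null, normalized enrichment scores and
    Benjamini-Hochberg false-discovery control. Includes cross-stratum
    comparisons (top-list Venn overlaps, overlap-coefficient similarity,
    correlation-distribution tests, median-split biomarker association)
    and a latent-factor cohort simulator with planted co-expression
    modules that provides ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    fgsea,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
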