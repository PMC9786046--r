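Package: cholvar
Title: Rare-Variant Filtering and Classification for Cholesterol-Pathway Gene Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for prioritizing and classifying rare variants
    found by targeted sequencing of cholesterol-metabolism gene panels in
    cardiovascular cohorts. Implements a two-stage filter cascade (population
    allele frequency, then consequence/splice-proximity), a four-category
    pathogenicity classification (known mutations by curated-database phenotype
    matching; potential mutations by in-silico prediction consensus, a splice
    score-delta rule and truncating-variant auto-inclusion), gene-level and
    patient-level cohort aggregation up to carrier prevalence, carrier versus
    non-carrier group comparisons, and a seeded synthetic-cohort generator with
    ground-truth labels for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    optparse,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    vcfR,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
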