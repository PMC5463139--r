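Package: triokin
Title: Trio Exome Variant Filtering and Rare-Variant-Sharing Consanguinity Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for family-based (trio and parent-child duo) whole-exome
    variant prioritisation: Mendelian segregation classification (recessive
    homozygous, dominant, de novo, compound heterozygous with parental-origin
    phasing), a rarity / nonsynonymous / in-silico-deleteriousness filter
    cascade, gene-panel candidate scans, and a resampling statistic that
    screens parent pairs for cryptic consanguinity by comparing observed
    rare-variant sharing against its Hardy-Weinberg expectation. A synthetic
    exome generator (site frequency spectrum, pedigree gene dropping,
    annotation labels, ground-truth injection) makes every stage testable at
    desk scale without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    vcfR,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
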