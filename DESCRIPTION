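Package: panelburden
Title: Germline Truncating-Mutation Burden Testing in Gene Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Filters annotated germline variant calls down to rare
    protein-truncating mutations, estimates population-specific background
    mutation rates normalized by per-individual callable sites, and tests
    whether a gene panel is enriched for truncating mutations relative to
    coverage-adjusted random expectation using an exact Poisson rate test
    with a callable-site offset. Includes Fisher exact and Mann-Whitney
    between-group comparisons, pooled multi-cohort meta-analysis, and a
    synthetic cohort generator (annotated VCF, coverage profiles, region
    BEDs, ground-truth manifest) for end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    stringr,
    rlang,
    ggplot2,
    generics,
    GenomicRanges,
    IRanges,
    vcfR,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
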