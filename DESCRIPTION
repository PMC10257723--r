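Package: lethalscan
Title: Detecting Recessive Lethal Alleles Through a Deficit of Homozygosity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to detect sequence variants and gene-level loss-of-function
    units whose homozygotes are depleted in large phased population cohorts.
    Expected homozygote counts are computed from per-population allele
    frequencies under Hardy-Weinberg equilibrium; strong deficits (observed at
    most 10% of expected) are flagged and tested with a one-sided Poisson
    test; an empirical false discovery rate is calibrated against intergenic
    variants binned by expected count; predicted loss-of-function variants are
    collapsed into gene-level biallelic genotypes (geneLOF) for a gene-based
    scan and a knockout catalogue; downstream inference covers gene-set
    over-representation (conditional-MLE Fisher odds ratios) and miscarriage
    excess among carrier couples with nearest-neighbour matched controls. A
    seeded multi-population cohort simulator with per-individual inbreeding,
    planted recessive-lethal variants and couple reproductive histories makes
    every stage testable without access to individual-level cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    jsonlite,
    Matrix,
    purrr,
    readr,
    rlang,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
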