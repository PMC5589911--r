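Package: xcitrace
Title: Allele-Specific Expression Analysis of X Chromosome Inactivation
    in Single-Cell RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying X chromosome inactivation (XCI) and dosage
    compensation from single-cell RNA-seq of early embryos. Calls
    monoallelic and biallelic expression from per-SNP allele read counts
    under stringent coverage and annotation filters, derives embryo-level
    gene informativeness, tracks biallelic and monoallelic expression
    fractions across developmental stages, and computes the dosage
    statistics (per-cell sums and medians of biallelically expressed
    X-linked genes, gene-wise female-to-male expression ratios, and
    X-to-autosome expression ratios) that discriminate X inactivation from
    X dampening. Includes expression-based embryo sexing and ploidy
    screening, and a seeded cohort simulator with binomial allele sampling
    for end-to-end validation under controlled X-regulation scenarios.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
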