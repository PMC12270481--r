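Package: xciae
Title: X-Chromosome Inactivation Escape Calling from Allele-Specific Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects human females with non-mosaic X-chromosome inactivation
    (nmXCI) from bulk RNA-seq allele-specific expression at heterozygous
    X-linked SNPs, and directly classifies X-linked genes as escaping,
    inactive or variable across tissues and individuals. Implements the
    allelic-expression screen (median nonPAR AE above 0.475), WES/WGS
    genotype merging and filtering, one-SNP-per-gene selection, a one-sided
    binomial test of inactive-X expression against a 2.5 percent null with
    per-tissue FDR correction, cross-tissue and cross-individual consensus
    calls, and automated curation rules for over-dispersion artifacts.
    A synthetic allele-count generator with configurable XCI skew, escape
    fractions, reference-mapping bias and beta-binomial over-dispersion
    stands in for access-controlled donor data.
License: MIT + file LICENSE
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
    rlang,
    stats,
    utils,
    vcfR,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
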