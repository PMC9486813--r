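Package: nshlcarrier
Title: Carrier Screening for Nonsyndromic Hearing Loss from Genome Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reproducible pipeline for estimating carrier status and
    projected disease frequency for nonsyndromic hearing loss (NSHL) in a
    genome-sequenced cohort. Curates a gene panel with per-mode gene-disease
    validity, screens catalogued pathogenic and likely pathogenic sequence
    variants with depth and call-rate quality control, filters copy-number
    events by coding overlap, size and syndromic critical regions, aggregates
    per-variant and per-gene allele frequencies across molecular mechanisms,
    projects autosomal-recessive affected frequency via the Hardy-Weinberg
    equation, classifies consanguinity evidence from runs of homozygosity, and
    compares allele counts against a reference cohort with a two-tailed Fisher
    exact test and Benjamini-Hochberg false-discovery-rate adjustment. A
    seeded synthetic-cohort generator produces complete input bundles so every
    stage is testable without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    IRanges,
    jsonlite,
    purrr,
    readr,
    rlang,
    S4Vectors,
    stats,
    stringr,
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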