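Package: hemoseq
Title: Targeted Case-Control Resequencing Analysis for Venous Thrombosis Gene Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end analysis pipeline for barcoded, multiplexed targeted
    resequencing of hemostasis gene panels in a case-control design, as used in
    pilot sequencing studies of deep vein thrombosis. Provides a synthetic
    cohort and read simulator, barcode demultiplexing, PCR-duplicate and
    mapping-quality read filters, pileup-based variant calling with
    allele-balance and strand-bias quality control, construction of a
    cross-sample genotype matrix with PLINK PED/MAP export, single-variant
    Fisher exact association screening with minor-allele-frequency and
    missingness filters, rare-variant collapsing (burden) tests, power-gated
    two-stage replication, variant consequence annotation against a toy gene
    model, site-frequency-spectrum summaries, and callset/genotype concordance
    reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
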