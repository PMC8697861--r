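Package: crisprstop
Title: Stop-Codon-Introducing Base Editing Guide Design and Amplicon
    Quantification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Design tools for CRISPR-STOP knockout screens with cytidine
    base editors such as Target-AID: enumeration of Cas9 protospacers with
    an NGG protospacer-adjacent motif, extraction of the deaminase editing
    window (16-19 bp upstream of the PAM), in-silico C-to-T editing and
    premature stop-codon prediction across the open reading frame, and
    intersection of guides across panels of homologous (e.g. proviral)
    genomes. Also quantifies window-restricted C-to-T substitution from
    targeted amplicon deep-sequencing reads (alignment, pileup, per-read
    conversion calls), and ships a seeded simulator that generates diverged
    genome families with conserved guide sites and amplicon FASTQ read sets
    with known edit fractions for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    S4Vectors,
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
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
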