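Package: chiahub
Title: Downstream Annotation of ChIA-PET Chromatin Loops, Hubs and
    Cis-Regulatory Elements
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Annotates ChIA-PET loop calls with the regulatory layers used in
    plant 3D-genome studies: anchor versus basal classification of ChIP-seq
    peaks and genes, loop span and promoter/intergenic categorisation,
    rule-based classification of accessible cis-regulatory elements (proximal
    and distal, active/poised/bivalent) with nearest and long-range target
    genes, chromatin-hub detection with transcription-factor target enrichment
    and two-condition disassembly classification, seed-gene connectivity
    networks, distance-matched co-expression nulls, and a lightweight
    contact-map architecture layer (binning, iterative-correction balancing,
    A/B compartment eigenvector calls, aggregate chromosome analysis, and
    interacting-domain segmentation). A seeded synthetic-data generator plants
    known loop categories, expression effects and hub changes so every stage
    is testable without sequencing data.
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
    rlang,
    readr,
    stringr,
    ggplot2,
    generics,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    rtracklayer,
    withr
Config/testthat/edition: 3
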