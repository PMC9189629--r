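Package: tcrspot
Title: Spatially Resolved T Cell Receptor Clonotypes from Visium Amplicon Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies T cell receptor beta (TCRbeta) clonotypes from targeted
    amplicon read 2 sequences of a Visium spatial gene expression library,
    links each clone-supporting read to its capture spot through the 16-nt
    spatial barcode and 12-nt UMI carried on paired read 1, deduplicates by
    (barcode, UMI), and builds a spot-by-clone UMI count matrix together with
    repertoire statistics (Shannon diversity, sequencing saturation, UMIs per
    spot) and quality-control diagnostics for off-tissue capture and B cell
    receptor cross-calling. Includes a full synthetic-data generator (segment
    references, primer pools, tissue positions, placed repertoires, paired
    FASTQ reads with PCR duplication and sequencing error, and ground-truth
    tables) so that every stage is testable without external sequencing data,
    and an import adapter for MiXCR-format clone tables and per-clone read
    files.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    S4Vectors,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
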