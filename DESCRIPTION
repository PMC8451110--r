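Package: nsltpkit
Title: Genome-Wide Identification and Characterization of Plant
    Non-Specific Lipid Transfer Proteins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native toolkit for genome-wide surveys of the plant
    non-specific lipid transfer protein (nsLTP) family. Screens candidate
    proteomes for the diagnostic eight-cysteine motif (8CM) with signal
    peptide, GPI-anchor, proline-rich and storage-protein filters; profiles
    physicochemical properties (pI, molecular weight, instability, aliphatic
    index, GRAVY) with ExPASy-compatible scales; classifies family members
    into the Edstam types (1, 2, C, D, E, F, G, X) from cysteine spacing,
    intron position and GPI status; builds cysteine-anchored alignments,
    p-distance matrices and neighbour-joining trees with bootstrap support;
    maps intron positions relative to the eighth cysteine codon and detects
    tandem and segmental gene duplications; scans 1.5 kb promoter regions
    for IUPAC-degenerate cis-acting elements; and summarizes tissue FPKM
    matrices and qRT-PCR tables with the 2^-ddCt method. A fully seeded
    synthetic-cohort generator emits proteomes, genomes, promoters and
    expression tables with a ground-truth manifest so every stage is
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    rtracklayer,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
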