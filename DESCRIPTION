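Package: dyadmapr
Title: Nucleosome Dyad Mapping, Peak Accessibility Classes and Motif
    Sampling from Fragment-Level Chromatin Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for fragment-level analysis of chromatin structure around
    transcription-factor binding sites: conversion of paired-end reads to
    fragments, mono-nucleosomal length filtering and dyad (fragment midpoint)
    extraction; anchor-centred signal matrices, metaplots and
    reference-normalized log2-ratio heatmaps; a three-class accessibility
    classifier for transcription-factor peaks (newly accessible,
    constitutively accessible, constitutively inaccessible) from
    transposase-accessibility fragment counts; IUPAC consensus motif scanning
    with peak-excluded motif-sampling enrichment against random genomic
    background; and a synthetic fragment-data generator with planted phased
    nucleosome arrays and ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    IRanges,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
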