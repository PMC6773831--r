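Package: numtaudit
Title: In Silico Audit of nuMT-Induced Reference Bias in Mitochondrial
    Variant Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies how nuclear sequences of mitochondrial origin (nuMTs)
    confound short-read alignment and mitochondrial variant calling. Generates
    synthetic mitochondrial and nuclear references with planted nuMT copies,
    simulates exhaustive sliding-window sequencing fragments, enumerates every
    possible single-nucleotide variant, aligns fragments with a deterministic
    best-hit (minimum-mismatch) aligner, and measures per-variant coverage loss
    and the resulting downward bias in observed heteroplasmy (minor allele
    frequency). Includes a haplotype background scan that measures how a
    haplogroup-defining SNP changes the coverage loss of surrounding variants,
    a shifted-genome breakpoint scan for circular references, and a SAM bridge
    for auditing external aligners.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    stringr,
    readr,
    ggplot2,
    rlang,
    generics,
    data.table,
    Biostrings,
    Rsamtools,
    rtracklayer,
    S4Vectors,
    jsonlite,
    GenomicRanges,
    IRanges,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    VariantAnnotation,
    withr
Config/testthat/edition: 3
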