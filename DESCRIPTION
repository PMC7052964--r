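Package: genomescreens
Title: Window-Based Synteny Blocks and Comparative Genomic Screens for
    Yeast Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Comparative-genomics screens for small eukaryotic (yeast)
    genomes built around plain tables: window-based synteny-block
    detection from whole-genome alignment coordinates (MUMmer
    show-coords or PAF), average nucleotide identity from codon
    alignments, a gene-family expansion screen with hypergeometric GO
    enrichment under Bonferroni correction, an Alien Index screen for
    horizontal gene transfer from lineage-partitioned BLAST best hits,
    and SNP-density classification of loss-of-heterozygosity regions.
    Ships seeded synthetic-genome generators with exact ground truth so
    every stage is testable without external data or aligners.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    SummarizedExperiment,
    VariantAnnotation,
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
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
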