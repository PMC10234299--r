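Package: asmgaps
Title: Gap and Structural-Variant Evaluation of Phased Genome Assemblies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Evaluates phased (haplotype-resolved) diploid genome assemblies
    against a complete reference using contig-to-reference alignments in PAF
    format. Detects assembly gaps between contig-end alignments, annotates
    contig breaks against feature tracks (segmental duplications, centromeric
    satellites, low-complexity GA/TC and AT tracts) with permutation-based
    enrichment, classifies intra-contig alignment discontinuities as sequence
    expansions or contractions, finds multi-coverage and embedded-contig
    regions with windowed copy-number classification, sizes dinucleotide
    low-complexity tracts by binned Z-scores, and validates assemblies by
    long-read gap spanning and megabase-block phasing concordance. Includes a
    deterministic synthetic-data generator that plants ground-truthed gaps,
    inversions, expansions, contractions and embedded contigs for end-to-end
    testing without external data.
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
    stringr,
    rlang,
    ggplot2,
    generics,
    stats,
    IRanges,
    GenomicRanges,
    S4Vectors,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
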