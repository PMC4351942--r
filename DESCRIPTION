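Package: teloci
Title: Transposable Element Insertion Site Detection from Paired-End Resequencing Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Locates non-reference transposable element (TE) insertion sites in a
    genome from paired-end whole-genome resequencing reads. Reads are aligned to a
    combined reference (genome plus the TE sequence), classified into background,
    cross and clipped pairs, clustered into candidate insertion loci, filtered on
    mapping quality, depth and support, and refined to exact breakpoints with
    target-site duplications from soft-clipped reads. Each call is typed
    heterozygous or homozygous with an exact binomial test on supportive versus
    background read-pair counts. Includes a paired-end read simulator with TE
    mutagenesis and truth tables, a benchmark evaluator, and GFF3-based
    exon/intron/intergenic annotation with a permutation test for genic enrichment.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    GenomicAlignments,
    GenomicRanges,
    generics,
    ggplot2,
    IRanges,
    jsonlite,
    purrr,
    readr,
    rlang,
    Rsamtools,
    rtracklayer,
    S4Vectors,
    stats,
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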