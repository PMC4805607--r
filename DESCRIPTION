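Package: pseudolap
Title: Scored Genomic Intersection of Pseudogenes and Long Non-Coding RNAs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Genome-wide positional intersection of pseudogene and long
    non-coding RNA (lncRNA) annotation sets. Implements reciprocal-fraction
    span-span and exon-exon overlap scoring, strand-aware classification of
    transcription evidence from full-length cDNAs and ESTs (with 3' EST
    orientation normalization), chained evidence intersections yielding
    high-confidence bidirectionally transcribed pseudogene-lncRNA loci,
    positional redundancy elimination and multi-catalog non-redundant merging,
    piRNA exonic-overlap support, GWAS SNP proximity annotation, and a pooled
    two-proportion z-test for enrichment comparisons. Includes a deterministic
    synthetic fixture generator with a planted truth table so the whole
    pipeline is testable without genome-scale downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr (>= 1.1.0),
    tidyr,
    purrr,
    tibble,
    readr,
    stringr,
    rlang,
    ggplot2,
    generics,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
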