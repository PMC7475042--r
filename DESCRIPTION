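Package: sunCN
Title: Paralog-Specific Allele Counting for Segmental Duplications Using
    Singly Unique Nucleotides
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates per-paralog allele counts of near-identical
    segmentally duplicated genes (the NOTCH2/NOTCH2NL family) from
    whole-genome sequencing depth and pileup allele frequencies at
    singly unique nucleotides (SUNs). Implements read-depth-ratio
    estimation of combined allele count on a paralog-masked reference,
    SUN derivation from locus sequences, population filtering of SUN
    markers, per-locus allele-count genotyping with subtraction and
    ratio splitting for recently converted paralog pairs, interlocus
    gene-conversion profiling along SUN tracks, functional-variant
    dosage quantification, population allele-count distribution tests
    (Kruskal-Wallis, Dunn, Kolmogorov-Smirnov, Holm), and a fully
    seeded synthetic cohort generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
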