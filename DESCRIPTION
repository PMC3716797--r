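Package: plastidcomp
Title: Comparative Analysis of Red Algal Plastid Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparative organelle genomics on circular replicons:
    GenBank flat-file input and output, open-reading-frame detection on
    circular genomes, per-genome composition statistics (G+C content,
    intergenic space, start-codon usage), gene-name harmonization and
    core/clade-shared/unique gene-content partitioning across genomes,
    tRNA isoacceptor repertoire comparison, and double-cut-and-join (DCJ)
    rearrangement distances from shared single-copy gene orders. A
    synthetic-genome generator with recorded ground truth (inversions,
    gene losses and gains applied down a clade tree) makes every stage
    testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    IRanges,
    methods,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
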