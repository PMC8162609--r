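Package: pancraft
Title: Recovering Missing Gene Products from Unmapped Reads and
    Bacterial Pan-Genome Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A two-stage comparative-genomics toolkit for bacterial genomes.
    Stage one recovers gene products missing from a reference assembly by
    partitioning sequencing reads into mapped and unmapped sets with a k-mer
    seed-and-extend classifier, assembling the unmapped fraction with a de
    Bruijn unitig assembler, calling open reading frames, and appending
    assembled coding sequences with no similarity to the annotated reference.
    Stage two performs pan-genome analysis on the updated genomes: gene-family
    clustering by all-vs-all protein similarity with e-value, identity and
    coverage filters, permutation pan/core/new-gene accumulation curves,
    Heap's-law fitting of the new-gene curve with an open/closed verdict,
    unique-gene and gene-sharing summaries, and pan-matrix distance trees
    (neighbor-joining and UPGMA). A synthetic-data module generates
    multi-strain pangenomes with known family structure, simulated reads, and
    planted missing-gene scenarios so the whole pipeline is testable without
    external downloads. Runs are resumable through a file-based step-state
    store.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    ape,
    igraph,
    jsonlite,
    rlang,
    ggplot2,
    stats,
    utils,
    tools,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
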