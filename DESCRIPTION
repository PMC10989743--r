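Package: microtrace
Title: Microbial Identification and SNP-Based Source Tracking from
    Amplicon and Whole-Genome Sequences
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Three desk-scale microbiology pipelines behind one interface:
    (1) amplicon-based identification that takes paired FASTQ reads through
    sliding-window quality trimming, pair merging, primer removal,
    dereplication, error-profile denoising into amplicon sequence variants
    (ASVs), and best-hit taxonomy with lowest-common-ancestor tie breaking;
    (2) whole-genome identification of assembled contigs by single-copy
    housekeeping-gene voting followed by fragment-based average nucleotide
    identity (ANI), plus MLST typing and best-hit protein annotation; and
    (3) alignment-free SNP discovery from k-mer contexts across genomes,
    with optional reference anchoring, SNP matrices, p-distances and
    neighbor-joining trees. A deterministic synthetic-data generator
    (random genomes, mutated derivatives, simulated 16S amplicon reads for
    the V3-V4, V4 and V4-V5 regions, toy housekeeping-gene and MLST
    databases) makes every stage testable without downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    ape,
    data.table,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
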