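Package: fishprobes
Title: Primary and Readout Probe Design for Sequential smFISH
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Designs ordered oligonucleotide probe sets for sequential
    single-molecule fluorescence in situ hybridization (smFISH). From a genome
    FASTA and gene models it extracts isoform-consensus target regions, tiles
    35-nt binding-site candidates, applies GC-content, homopolymer and
    masked-base filters, screens candidates against a transcriptome-wide k-mer
    off-target index, resolves overlaps and trims each gene to at most 40
    probes closest to 55% GC, generates random transcriptome-orthogonal 20-nt
    readout probes, assembles 141-nt primary probes with AA/TAAT linkers, and
    schedules hybridization rounds across fluorophore channels. Includes a
    seeded synthetic-transcriptome generator with planted features and a
    brute-force oracle for end-to-end validation.
License: MIT
Encoding: UTF-8
Imports:
    BiocGenerics,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    seqinr,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
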