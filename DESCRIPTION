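Package: prophagemine
Title: Multi-Signal Prophage Detection, Attachment-Site Finding and Moron
    Screening in Bacterial Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects candidate prophage regions in annotated bacterial genomes
    from the genomic signals that distinguish integrated phages from host
    background (phage-gene clustering density, median predicted-protein
    length, transcription-strand runs, GC content and GC skew anomalies),
    applies consensus and size-based curation rules, classifies regions by
    phage-core-gene completeness and lysogeny evidence, locates candidate
    attachment sites as shared direct repeats near tRNA genes, and screens
    for moron (lysogenic-conversion) genes via sigma-70 promoter scanning,
    rho-independent terminator prediction and local GC anomaly. Ships the
    fully transcribed 90-ORF gene table of the temperate Paraburkholderia
    phage phi437 as a validation fixture and a synthetic-genome generator
    with machine-readable planted truth for end-to-end benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    Biostrings,
    GenomeInfoDb,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    methods,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
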