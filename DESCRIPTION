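Package: redcontacts
Title: RNA-DNA Proximity-Ligation Contact Analysis for Circular
    Prokaryotic Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis of RNA-DNA proximity-ligation (RedC-style) sequencing
    data from single circular prokaryotic replicons. Parses bridge-containing
    chimeric read pairs into DNA, RNA 3' and RNA 5' portions, maps them with
    an exact-match unique mapper, and assembles filtered RNA-DNA contacts.
    Provides strand-aware gene assignment, binned whole-genome contact maps,
    cis/trans interval-preference statistics, upstream/downstream
    nascent-transcript profiles, cumulative operon contact maps, and
    background-normalized contact statistics for noncoding RNAs versus gene
    activity. Includes a synthetic-data generator that emulates operonic
    transcription, polymerase drag of polycistronic transcripts, activity
    coupling of ribosomal RNA and depletion of 6S RNA, down to raw paired
    reads with a ground-truth sidecar, so the full pipeline is testable
    without external data.
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
    Matrix,
    methods,
    rtracklayer,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
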