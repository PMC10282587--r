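Package: glassarch
Title: Genome Architecture and Biomineralization Screens for Compact
    Animal Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analyses of genome architecture and biomineralization
    candidates in compact animal genomes, motivated by glass sponge
    (Hexactinellida) genomics. Detects genes nested inside the introns of
    other genes, extracts microsynteny blocks from pairwise protein hits
    with Fisher's exact scaffold-pair enrichment tests, discovers
    trans-spliced leader sequences from soft-clipped long-read
    alignments, screens proteomes for amino-acid compositional bias
    against a reference proteome, scans cathepsin-L style cleavage
    motifs, and aggregates assembly metrics by weighted ranks. Seeded
    synthetic-data generators emit annotations, ortholog pairs, long
    reads, proteomes and metric tables with ground truth so every stage
    is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicAlignments,
    GenomicRanges,
    graphics,
    IRanges,
    rtracklayer,
    S4Vectors,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
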