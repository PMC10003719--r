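Package: flipmir
Title: MicroRNA Seed Targeting of Non-B DNA Flipons in Promoters
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis toolkit for the interaction between conserved microRNA
    seed sequences and non-B-DNA-forming elements (flipons: Z-DNA,
    G-quadruplex, SIDD and H-DNA motifs). Scans genomic DNA for perfect
    7-mer seed matches on both strands, classifies each match against flipon
    intervals as motif (M), motif-junction (MJ) or junction (J) sites,
    assigns genomic features and regulatory context (cCRE, CTCF,
    LINE/LTR repeats), profiles flipon and seed-match density in 100 bp
    windows around transcription start sites, takes a promoter heptamer
    census, calls the conformational effect of each interaction (promotion
    or suppression of G-quadruplex or Z-DNA, wobble-pair hairpin
    feasibility, Z-quadruplex candidates), and tests interval-overlap
    significance by Monte-Carlo shuffling. A synthetic-data generator with a
    machine-readable truth manifest makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer,
    jsonlite,
    zoo,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
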