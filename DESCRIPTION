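Package: phagecg
Title: Comparative Genomics of Small Circular ssDNA Phage Genomes
Version: 1.0.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tested pipeline for the comparative analysis of small circular
    single-stranded DNA bacteriophage genomes (Microviridae-scale, 4-6 kb):
    circular genome assembly from exact-overlap subclone fragments, open
    reading frame prediction with origin wraparound, nucleotide composition
    and coding-capacity statistics, tetranucleotide z-score genome signatures
    compared by regression R-squared, affine-gap global and local protein
    alignment with Karlin-Altschul E-values, greedy incremental protein
    clustering at an identity threshold, pangenome shared/unique gene
    determination, and UPGMA dendrograms from membership or functional-count
    profiles. Includes a seeded synthetic-data generator that evolves
    orthologous gene families along a known tree so every stage can be
    validated against ground truth without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    jsonlite,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    withr
Config/testthat/edition: 3
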