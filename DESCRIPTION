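Package: methoxr
Title: Comparative Genomics and Metagenomics of Aerobic Methoxydotrophy
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Analysis pipeline for studying the genomic basis and environmental
    distribution of methoxydotrophy (growth on the methoxy groups of
    lignin-derived aromatic compounds) in Methylobacterium. Provides KEGG
    Orthology presence/absence profiling of aromatic-catabolism markers with
    Fitch parsimony gain/loss reconstruction, tetranucleotide genome-signature
    (delta-star) characterization of horizontally acquired catabolic islands,
    a minimal likelihood-based phylogenetic placement engine for
    metagenome-derived vanillate-monooxygenase (vanA) gene fragments, an
    ecosystem-level survey stage, growth-assay numeric helpers, and a
    synthetic-data generator that produces every input class with known
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    jsonlite,
    phangorn,
    stats,
    utils
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
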