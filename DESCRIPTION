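Package: tripan
Title: Tri-Genome Pan-Genome Comparison and Variant Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Comparative analysis of three closely related genome assemblies
    in the style of rice pan-genome studies: a built-in unique-k-mer anchor
    chaining whole-genome aligner (with an escape hatch for MUMmer
    show-coords files), one-to-one alignment filtering, classification of
    every base of the three genomes as core, dispensable or
    genome-specific, SNP and small-indel extraction with functional effect
    annotation, a six-category classifier for large (>=10 bp) structural
    variants, presence-absence variation calling with identity and length
    filters, read-depth copy-number variation calling, and Fisher
    exact-test gene-set enrichment with Benjamini-Hochberg correction.
    Includes a three-genome evolution simulator emitting machine-readable
    truth sets so every stage is testable by truth recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    methods,
    stats,
    utils,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
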