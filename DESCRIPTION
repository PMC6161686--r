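Package: mirlocus
Title: Small RNA Locus Curation and miRNA Biogenesis Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for curating microRNA loci from small RNA sequencing data
    in AT-rich genomes, modeled on the biology of the social amoeba
    Dictyostelium discoideum. Implements hierarchical classification of
    small RNA reads, duplex calling from read stacks on folded hairpin
    precursors under the five high-confidence miRNA criteria plus
    Dicer-knockout dependence, primary-transcript extent and readthrough
    analysis from long RNA coverage, untemplated oligo(A) tail detection,
    and discovery of the T-run plus G transcription start site motif.
    A seeded synthetic-data generator with planted ground truth supports
    end-to-end recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    Rsamtools,
    rtracklayer,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
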