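Package: mitomarker
Title: Comparative Mitogenomics and Phylogenetic Marker Evaluation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for comparative analysis of annotated mitochondrial
    genomes and for ranking individual mitochondrial genes as phylogenetic
    markers. Reads GenBank flat files and extracts the canonical 37-gene
    complement, computes base composition, AT/GC skews, start/stop codon
    usage (including incomplete stops), relative synonymous codon usage and
    amino-acid proportions under the invertebrate mitochondrial code;
    estimates nucleotide diversity (pi) per gene and in sliding windows;
    estimates Ka/Ks by the Nei-Gojobori (1986) pathway method with
    Jukes-Cantor correction; scores per-gene trees against a reference tree
    with the K tree score; and synthesises the per-gene statistics into a
    marker-ranking report. Seeded simulators for trees, nucleotide and
    codon alignments, and toy annotated mitogenomes make every stage
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    Biostrings,
    phangorn,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
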