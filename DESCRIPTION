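Package: mitoaudit
Title: Codon-Aware Audit of Mitochondrial Initiation Codons and Gene Order
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparative annotation of metazoan mitochondrial
    genomes. Reads annotated mitogenomes (GenBank flat files or FASTA plus
    GFF3), extracts orthologous protein-coding genes across taxa, aligns
    their translations under mitochondrial genetic-code variants (NCBI
    translation tables 1, 5 and 9), and audits annotated initiation codons
    against the cross-taxon alignment: confirming starts, proposing
    frame-preserving boundary corrections, and flagging candidate
    alternative initiation codons such as ATT, ATC and TTG. Also encodes
    gene arrangements as signed circular permutations and quantifies
    gene-order conservation (breakpoint distances, conserved blocks,
    two-block interchanges). A synthetic mitogenome generator with planted
    ground truth makes every pipeline stage testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    rtracklayer,
    jsonlite,
    withr,
    yaml,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
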