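Package: tetmine
Title: Mining and Characterization of Plant Tetraspanin Gene Families
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for genome-wide identification and characterization of
    plant tetraspanin gene families. Classifies candidate proteins by
    transmembrane topology (four TM helices, extracellular loops of unequal
    size, a cysteine-rich EC2 carrying the GCCK/RP signature, short
    cytoplasmic tails), computes pairwise identity/similarity matrices and
    per-domain conservation from multiple alignments, builds neighbor-joining
    trees with bootstrap support, derives intron counts, lengths and phases
    from gene models, calls tandem and segmental duplications from gene
    position and colinearity-anchor tables, scans promoter windows for IUPAC
    cis-regulatory elements, and computes relative expression from qPCR Cq
    tables by the delta-delta-Ct method. A seeded synthetic-data module
    generates proteomes, annotations and Cq tables with known ground truth so
    every stage of the pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    ape,
    rtracklayer,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    pheatmap
Config/testthat/edition: 3
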