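Package: sixframer
Title: Proteogenomic Peptide Discovery from Six-Frame Genome Translation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Discovery of protein-coding regions directly from tandem mass
    spectrometry data by searching spectra against a coordinate-tracked
    six-frame translation of a genome. Builds stop-to-stop putative protein
    databases with reversed decoys and an exon-junction peptide database,
    runs a two-stage target/decoy search with decoy-based false discovery
    rate control, maps identified peptides back to genomic coordinates and
    classifies them against gene annotation, applies pseudogene, repeat and
    conservation filters, and validates candidates by common-ion spectral
    comparison against synthetic-peptide spectra with an empirical
    permutation null. Includes a deterministic synthetic-fixture generator
    (genome, annotation, auxiliary tracks and spectra with planted ground
    truth) so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    igraph,
    seqinr,
    optparse
Config/testthat/edition: 3
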