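Package: ribotranskit
Title: Ribosome Profiling Analysis Toolkit for Prokaryotes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for bacterial ribosome profiling (Ribo-seq) data:
    a seeded simulator of genomes, annotations and footprint/RNA alignments;
    A-site offset calibration, triplet periodicity and metagene diagnostics;
    TMM-normalized RPKM and translation efficiency; moderated-t differential
    testing of translation efficiency (DiffTE) and of per-codon ribosome
    occupancy at the E/P/A sites (DiffCO); ORF enumeration with ORFscore
    periodicity scoring and sORF filtering with mass-spectrometry peptide
    cross-referencing; and two small CNN-Transformer models for translation
    initiation site and sORF prediction, trained natively in R.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    data.table,
    stats,
    utils,
    methods,
    tools,
    Biostrings,
    IRanges,
    GenomicRanges,
    Rsamtools,
    GenomicAlignments,
    rtracklayer,
    S4Vectors,
    edgeR,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    limma,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
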