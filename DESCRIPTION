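Package: marstools
Title: Preprocessing Toolkit for Plate-Based MARS-seq Experiments
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Standalone preprocessing of plate-based MARS-seq single-cell
    RNA-seq experiments: validation of sequencing-batch, amplification-batch
    and wells-cells metadata with hard-stop checkpoints; extraction of the
    pool barcode, cell barcode and UMI from paired reads with quality
    filtering; chunked FASTQ splitting; augmentation of a genome FASTA and
    GTF with ERCC spike-in sequences; conversion of MARS-seq read pairs to a
    10X-style layout with composite-barcode whitelist generation for
    splice-aware CB/UMI counting aligners; and demultiplexing of aligned
    reads into a well-by-gene UMI count matrix with exact or directional UMI
    collapse. A seeded simulator generates complete synthetic experiments
    with ground-truth counts so every stage is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    ShortRead,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomicAlignments,
    SummarizedExperiment,
    Matrix,
    Rsamtools,
    rtracklayer,
    jsonlite,
    yaml,
    readxl
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
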