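Package: tnbarseq
Title: Mapping, Counting and Fitness Analysis of Barcoded Transposon
    Insertion Libraries
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for randomly barcoded transposon insertion sequencing
    (RB-TnSeq) and other DNA-barcoded strain libraries. Extracts barcodes
    and host junction sequences from raw reads using a construct anchor,
    maps insertions to a reference genome and annotates them against a
    GFF3 file, quantifies barcode abundance across samples into a count
    matrix, and identifies genes under positive or negative selection
    with a four-step count analysis (median-of-ratios or control-barcode
    normalization, mean-variance modeling, negative-binomial barcode
    tests, and robust rank aggregation of barcode ranks into gene
    scores with permutation p-values). Includes wild-type control-barcode
    quality control via dilution-series regression and a fully seeded
    synthetic-data generator (genomes, insertion libraries, mapping
    reads, and selection screens with known ground truth) so every
    pipeline stage can be exercised without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    optparse,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
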