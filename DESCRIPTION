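Package: gcatex
Title: GC/AT Exon Classes, Splice-Signal Decoys, and Genomic Domain Context
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline linking nucleotide composition bias to splicing
    regulation. Classifies splicing-factor-activated exons into GC-rich and
    AT-rich classes from regulation tables, scores splice-signal features
    (branch-point candidates, U2 snRNA duplex hydrogen bonds, TNA and T-rich
    decoy motifs, junction folding stability), quantifies U1- versus U2-snRNP
    dependency with a subsampling randomization statistic (the V value),
    builds coverage metaprofiles and CLIP peak positional maps around splice
    sites, and assigns exons to isochore/TAD/LAD genomic domains. Includes a
    synthetic-genome generator with planted composition structure for
    end-to-end recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer,
    stats,
    tools,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
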