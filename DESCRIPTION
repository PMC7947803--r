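Package: natscan
Title: Identification and Characterization of Natural Antisense Transcripts
    from Stranded RNA-Seq
Version: 0.1.0
Authors@R:
    person("natscan", "developers", email = "natscan@example.org",
           role = c("aut", "cre"))
Description: A strand-aware pipeline for identifying and characterizing
    natural antisense transcripts (NATs) from stranded paired-end RNA-seq.
    Extracts antisense fragments within per-gene overlap-free zones,
    validates de novo antisense contigs against the source genome with
    BLAST coverage and identity filters, removes spurious contigs
    attributable to strand misassignment with a low-pass read-fraction
    filter, scores tissue-specific antisense enrichment between two brain
    regions, classifies sense-antisense pairs by the sign concordance of
    their developmental expression slopes, and filters contigs by
    cross-species sequence conservation. Includes a synthetic-data
    generator with full ground truth so every stage can be exercised
    against known answers.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    data.table,
    jsonlite,
    BiocGenerics,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    rtracklayer,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
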