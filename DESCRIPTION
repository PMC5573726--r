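Package: seedshift
Title: IsomiR Profiling and miRNA Annotation Auditing from Small RNA-Seq Reads
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to map small RNA-seq reads onto miRNA hairpin precursors,
    classify each read as an isomiR (5'/3' template offsets, non-templated 3'
    additions, substitutions), aggregate reads-per-million profiles, and audit
    miRBase-style mature annotations against the sequences a library actually
    contains: dominant-sequence calling, 5' seed-shift detection, cross-sample
    concordance, and position probability matrices for sequence logos. Includes
    a synthetic small-RNA read generator with exact ground-truth manifests, and
    seed-match target-site scanning to quantify how a shifted seed changes a
    3'UTR target repertoire. Ships a worked reference set for the miR-34 family,
    where the endogenously dominant miR-34b-5p is a 1-nt 5'-shifted variant of
    the annotated sequence.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    methods,
    purrr,
    readr,
    rlang,
    S4Vectors,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    rtracklayer,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
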