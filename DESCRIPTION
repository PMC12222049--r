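Package: bactgene
Title: Two-Stage Transformer Annotation of Bacterial Genes and Translation
    Initiation Sites
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Annotates bacterial genomes with a two-stage classifier built on a
    k-mer tokenized transformer encoder. Open reading frames are extracted from
    both strands, grouped by shared stop codon, and classified as coding or
    non-coding; within predicted-coding groups a second classifier scores
    60-nt windows around each in-frame start codon and the highest-probability
    translation initiation site is retained. Includes dataset construction
    (labeling, length-aware balancing, organism-held-out splits), training with
    AdamW and a linear warm-up/decay schedule, matched 5'+3' and 3'-end
    benchmarking against reference annotations, attention-map interpretability
    with attention-guided sequence disruption, and a synthetic-genome generator
    with planted genes for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    rtracklayer,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
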