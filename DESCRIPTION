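Package: broadscape
Title: Prioritizing Cell Identity Genes from Broad Epigenomic Domains
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Implements an epigenetic-landscape pipeline for prioritizing
    candidate cell identity genes. Broad enriched domains are called from
    aligned ChIP-seq or DNase-seq tags with a two-threshold Poisson
    seed-and-extend segmentation, summed to gene-level breadth, ranked per
    chromatin mark, and combined across marks by average rank. Top-ranked
    genes are scored by Fisher exact gene-set enrichment, by edge and
    transcription-factor counts in a gene regulatory network, by cumulative
    motif-to-TSS distance enrichment, and by chromatin-loop anchor overlap
    with an exact two-sample Poisson comparison. A synthetic-data generator
    with planted ground truth makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    Biostrings,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    rtracklayer
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
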