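Package: splicecall
Title: Splice Junction Detection, Classification and PSI Quantification
    from Short-Read RNA-seq Alignments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects splice junctions (including unannotated ones, intron
    retention and gene-fusion candidates) from aligned short-read RNA-seq
    data. Gapped-alignment evidence is collected from SAM/BAM files together
    with read-pair orientation, placement-ambiguous novel junctions are
    shifted toward annotated splice sites, junctions are classified by the
    annotation status of their two splice sites, and two percent-spliced-in
    (PSI) values are computed per junction by treating the absence of
    splicing at a site (read-through depth measured inside the putative
    intron) as a competing alternative. Tiered stringency filters, junction
    tables, per-gene summaries, and a synthetic fixture generator with a
    truth-based scorer are included so every stage can be exercised without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicAlignments,
    GenomicRanges,
    IRanges,
    Rsamtools,
    S4Vectors,
    ggplot2,
    methods,
    rtracklayer,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
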