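Package: cryptic3ss
Title: Cryptic 3' Splice-Site Discovery and Sequence-Context Analysis from
    Splice-Junction Tables
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects cryptic (previously unannotated) 3' splice sites from
    per-sample splice-junction count tables (the STAR SJ.out.tab dialect),
    pairs them with their canonical acceptors by a minimum-distance rule,
    quantifies per-sample percent-spliced-in (PSI) and tests differential
    cryptic acceptor usage between mutation groups. Characterizes the
    intronic sequence context of cryptic acceptors (per-position nucleotide
    composition with Fisher enrichment against control introns,
    consecutive-adenine run features near the branch-point region, six-mer
    enrichment) and provides the companion expression stage (RPKM, log2,
    quantile normalization, differential expression, PCA, hierarchical
    clustering). A synthetic-data generator plants cryptic acceptors with
    known distances, group-wise PSI, poly-A run intensity and
    nonsense-mediated-decay coupled expression so that every stage is
    testable against ground truth without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table,
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer,
    S4Vectors,
    limma,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
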