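Package: histoquant
Title: Weighted Multimapped Quantification of Repetitive Histone Transcripts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantifies highly repetitive replication-dependent histone gene
    families from RNA-seq alignments by weighting multimapped reads 1/n across
    their mapping loci (capped at 10), normalizes against randomly chosen
    unchanging genes via control-anchored geometric-mean factors with a 0.1
    floor for zero coverage, and tests canonical versus variant histone
    gene-set fold changes with two-sided t-tests. Companion analyses include
    reads-per-million expression filtering, Benjamini-Hochberg correction, a
    lightweight differential-expression substitute, CLIP cluster per-feature
    coverage and binding enrichment, cross-experiment concordance, and
    comparative-CT qPCR with oligo-dT to random-hexamer polyadenylation
    ratios. A deterministic synthetic-data generator provides ground truth
    for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    jsonlite,
    purrr,
    readr,
    rlang,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
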