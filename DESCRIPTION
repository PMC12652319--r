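Package: loopscape
Title: Chromatin Loop Calling, Differential Loop Classification, and
    CLIP Reproducibility Analysis on Binned Contact Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for integrative analysis of chromatin architecture from
    binned intra-chromosomal contact maps: distance-stratified loop calling
    with a binomial significance model, sample-specific/common differential
    loop classification, CTCF anchor annotation, aggregate peak analysis,
    diamond insulation scores, stratum-adjusted correlation coefficients,
    and compartment eigenvectors.  Includes a CLIP-seq crosslink-site
    pipeline (fixed-width peak standardization, per-replicate percentile
    reproducibility filtering, negative-control overlap filtering), a
    negative-binomial Wald test for count matrices, interval-overlap
    enrichment statistics with Fisher's exact test against random gene
    sets, and a seeded synthetic 3D-genome generator with planted
    compartments, TADs, loops, expression effects and crosslink tracks
    that serves as ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    Matrix,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    yaml,
    methods,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
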