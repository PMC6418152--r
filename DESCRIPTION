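Package: hirscan
Title: Interactivity Profiles and Highly Interacting Regions from Hi-C
    Contact Maps
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Transforms intra-chromosomal Hi-C contact maps into
    one-dimensional per-bin interactivity profiles, computed as the
    stationary distribution of a random walk on the observed-minus-expected
    contact network. Calls Highly Interacting Regions (HIRs) as runs of
    consecutive high-interactivity bins, characterizes them by percentile
    normalized signal-track enrichment, classifies them by principal
    component analysis followed by Ward clustering, and quantifies overlap
    of HIRs with genomic annotation sets against a uniform-genome
    expectation. Includes a synthetic-data generator with planted
    interaction hubs for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    rtracklayer,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
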