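Package: binclust
Title: Adaptive-Window Enriched-Region Calling and Broad-Signal
    Clustering for ChIP-Seq
Version: 0.1.0
Authors@R:
    person("binclust", "developers", email = "binclust@example.org",
           role = c("aut", "cre"))
Description: Calls enriched regions (ERs) from mapped ChIP-seq reads with an
    adaptive-size-window strategy in which the atomic unit is the "bin", the
    gap between two neighboring strand-shifted read 5' positions.  Sliding
    initial windows of a fixed bin count are shrunk into 3'-anchored step
    windows, scored by an upper-tail Poisson test against a local/global
    background, and significant final windows are merged into ERs.  ERs are
    clustered into short-ER clusters (SERs) via the fragment-rate-by-distance
    (FR-D) statistic and into long-ER clusters (LERs, broad domains) via the
    fragment-rate-by-reads-enrichment (FR-RE) statistic, with candidate
    connecting lengths drawn from percentiles of shuffled inter-region
    distances (PDNP).  Also provides signal ranking, motif-based reliability
    curves, gene association, a bivalent-domain candidate filter, CRISPR
    negative-selection screen prioritization, and a seeded read simulator
    with ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils,
    Rcpp,
    IRanges,
    GenomicRanges,
    S4Vectors,
    Rsamtools,
    jsonlite,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
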