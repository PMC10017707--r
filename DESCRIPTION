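Package: depscan
Title: Chromatin-State Screening of Oncogene Dependency from CUT&Tag Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Links chromatin state to oncogene dependency across a panel of
    tumor cell lines. Implements dependency scoring from cell-competition
    assays (log2 relative growth rates from sequential FACS fractions),
    binned trimmed-mean-of-M-values normalization of CUT&Tag tag counts,
    a cross-mark Kendall rank-correlation screen over cis-regulatory
    elements with concordance labeling and rank-rank hypergeometric
    overlap, combinatorial chromatin-state and transcription-factor
    co-binding classification, ROSE-style super-enhancer stitching with a
    tangent rank cutoff, and Tn5-insertion footprint quantification
    (flank height, footprint depth, relative footprint depth, bound and
    unbound calls). A synthetic-panel generator with recorded ground
    truth exercises the whole chain end-to-end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    data.table,
    jsonlite,
    mclust,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    withr
Config/testthat/edition: 3
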