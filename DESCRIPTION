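Package: chromage
Title: Enhancer Remodelling and Histone Acetylation Dynamics in Aging Tissue
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for age-related chromatin change in bulk
    tissue. Detects genome-wide histone-mark gain with a young-cohort
    z-score statistic on genomic bins, builds a cross-sample H3K27ac peak
    atlas, calls typical and super-enhancers by rank-ordering stitched
    distal regions (tangent cutoff), clusters enhancer and gene-expression
    trajectories across ordered age groups against integer model profiles
    with permutation significance, and links activated enhancers to their
    nearest genes with hypergeometric overlap scoring. Ships a synthetic
    aging-cohort generator with planted age-responsive loci so every stage
    is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    IRanges,
    S4Vectors,
    data.table
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
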