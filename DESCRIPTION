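Package: scdrisk
Title: Risk-Pattern Discovery for Sudden Cardiac Death Screening of Athletes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Consensus hierarchical-clustering pipeline for stratifying sudden
    cardiac death (SCD) risk from athlete pre-participation screening features.
    Provides the feature catalogs of the screening survey, cohort loading and
    min-max normalization, an agglomerative clustering engine over a grid of
    distance metrics and linkage criteria with full merge histories, dendrogram
    cutting driven by the R_k inter/intra-variability index, cross-run consensus
    and consolidation of minority (candidate risk) clusters, risk versus
    non-risk feature profiling, PCA projection of cohorts and new subjects, and
    a synthetic cohort generator emulating the screening survey's statistical
    structure.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    ape
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
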