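Package: scnapipe
Title: Somatic Copy Number Alteration Calling, Genome Altered Burden, and
    Immunogenomic Screens from Methylation-Array Copy Ratios
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for segment-level somatic copy number analysis of
    log2 copy ratio data such as that derived from methylation arrays.
    Provides recursive binary segmentation of bin-level copy ratios,
    cohort-wide three-component Gaussian mixture calling of gained, lost
    and neutral segments by expectation-maximization, per-sample percent
    genome altered (PGA), covariate-adjusted genome-wide screens of
    gene-level copy number against group labels or continuous genetic
    ancestry, germline copy number variant filtering against a
    normal-tissue cohort, per-locus Cox proportional hazards screens of
    censored outcomes, reference-based cell-type deconvolution of
    methylation beta values by constrained least squares, and
    correspondence-at-the-top concordance utilities. Includes a synthetic
    cohort generator with planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    limma,
    survival,
    pracma,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite,
    knitr,
    rmarkdown,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
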