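Package: tepra
Title: Enhancer-Activity Evolution Analysis for Transposable-Element
    Subfamilies from Tiled and Motif-Focused MPRA
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis toolkit for studying how enhancer activity evolves
    within a transposable-element (TE) subfamily assayed by massively
    parallel reporter assay (MPRA). Provides barcode-count aggregation and
    basal-normalised log2 enrichment scoring; a per-position association
    scan ("TE-WAS") relating sequence variation across subfamily copies to
    reporter activity, with information-content motif overrepresentation;
    ridge deconvolution of tiled reporter scores into per-nucleotide
    activity tracks with peak calling; sliding-window conservation tests
    against a consensus and exact plus simulated neutral motif-retention
    probabilities under a transition/transversion substitution model;
    interval-overlap enrichment against annotation sets; and a synthetic
    TE-subfamily/MPRA generator with planted motifs and known truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    Rcpp,
    S4Vectors,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    ape,
    knitr,
    rmarkdown
Config/testthat/edition: 3
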