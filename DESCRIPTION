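Package: amprearr
Title: Amplicon Rearrangement Junction Analysis for Extrachromosomal and
    Intrachromosomal Amplifications
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Characterizes structural-rearrangement junctions inside amplified
    genome regions (double minutes and homogeneously staining regions):
    two-sided microhomology calling at fusion seams, untemplated-insertion
    detection and flank variant scanning, a random-joining microhomology null
    model with an exact enrichment test, max-gap single-linkage breakpoint
    clustering, junction-arm adjacency linking and contig assembly,
    coordinated-junction-pair detection, binned read-depth segmentation of
    amplified intervals, and cross-passage junction-set comparison. Includes a
    seeded amplicon rearrangement simulator that emits junction tables, depth
    tracks and spanning sequences together with full generative truth for
    benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stringr,
    tibble,
    tidyr,
    withr,
    stats,
    utils,
    Biostrings,
    IRanges,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
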