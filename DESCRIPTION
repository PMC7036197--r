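Package: hicvis
Title: Visibility-Bias Correction and Distance-Sorted Contact Optimization
    for Hi-C Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Corrects the condensation-driven visibility bias of
    restriction-digestion based chromatin assays. Provides loess-based
    correction of binned 1D read counts for restriction-site density and
    GC content, calling of condensed and decondensed chromatin domains
    from Z-scored corrected tracks with a permutation false discovery
    rate, Distance Sorted Contact Optimization (DiSCO) of contact
    matrices with an iterative-balancing companion, the comparison
    statistics used to evaluate such tracks and domains, and a seeded
    synthetic-data generator with known ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    IRanges,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    limma,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
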