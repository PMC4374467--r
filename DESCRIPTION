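Package: morphoqtl
Title: Multivariate QTL Mapping of 3D Geometric Morphometric Shape in
    Experimental Crosses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Maps quantitative trait loci (QTL) for high-dimensional shape
    phenotypes in backcross populations. Provides generalized Procrustes
    analysis with object symmetry for 3D landmark configurations,
    extraction of the symmetric shape component and its non-zero
    principal-component basis, hidden-Markov genotype probabilities under
    a Carter-Falconer map function, multivariate Haley-Knott genome scans
    scored by Pillai's trace, permutation genome-wide thresholds,
    penalized forward/backward multiple-QTL model search with Bayes
    credible intervals, effect-size and anatomical-region decompositions
    of shape-change vectors, interval-to-gene overlap with hypergeometric
    enrichment, and a synthetic backcross generator with planted QTL for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    S4Vectors,
    IRanges,
    GenomicRanges,
    rtracklayer
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
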