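Package: secaller
Title: Super-Enhancer Calling and Regulatory Landscape Analysis from ChIP-seq Signal
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: ROSE-style identification of super-enhancers from ChIP-seq peak
    calls and tag signal: peak filtering, TSS exclusion, stitching of nearby
    peaks, input-subtracted tags-per-million density ranking and
    inflection-point classification of the ranked density curve. Downstream
    analyses assign protein-coding genes, lncRNAs, miRNAs and eQTL
    linkage-disequilibrium regions to enhancers by a 100-kb extension rule,
    partition enhancers and genes into cell-type-specificity modules across
    three conditions, contrast resting versus stimulated enhancer landscapes
    (top induced and repressed super-enhancers, seed-enhancer origins) and
    apply the accompanying two-sample t and Pearson chi-squared tests. A
    synthetic landscape generator with a ground-truth manifest exercises every
    stage without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
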