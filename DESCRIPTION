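Package: maizeUVB
Title: Elevational Differential Expression and Phenolic-Pathway Enrichment
    in Maize Landraces
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Downstream transcriptomic analysis of maize landraces collected
    from three elevational zones and grown in a common garden: median-of-ratios
    count normalization, per-gene negative-binomial differential expression
    with block adjustment and pairwise zone contrasts, expression-matched
    candidate gene-set enrichment using Yates-corrected chi-square tests, and
    resampling consensus hierarchical clustering of libraries. A seeded
    negative-binomial simulator emulating the 45-library split-plot design
    (3 zones x 5 landraces x 3 blocks) with a tunable candidate enrichment
    factor makes every stage testable without the original sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    ape
Suggests:
    testthat (>= 3.0.0),
    mclust,
    DESeq2,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
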