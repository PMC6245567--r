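Package: rxscape
Title: Visualizing Variation in Censored Prescription-Claims Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing nationwide variation in provider
    prescribing patterns from privacy-censored prescription claims
    tables, in the shape of the Medicare Part D Prescriber Public Use
    File. Builds sparse provider-by-drug claim matrices with the CMS
    small-cell censoring rule, derives per-provider compositional
    profiles at the drug or drug-class level, and summarises volume
    and diversity skew with the Gini concentration index. Providers
    are embedded in two dimensions by exact t-distributed stochastic
    neighbor embedding (t-SNE) after principal-component
    pre-processing, grouped by Ward agglomerative clustering, and
    compared across metropolitan areas and states via
    claims-per-enrollee region profiles, one-minus-correlation
    distances, classical multidimensional scaling with a
    label-permutation null, and Mantel-style distance-matrix
    correlation. A synthetic claims generator with planted specialty,
    volume and regional structure supports end-to-end testing without
    access to the federal download.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    grDevices,
    rlang,
    Matrix,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    ggplot2,
    vegan
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
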