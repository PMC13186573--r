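Package: PAApipe
Title: Detection and Coevolutionary Analysis of the Phenylacetic Acid
    Degradation Pathway
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Comparative-genomics toolkit for identifying and classifying
    the hybrid phenylacetic acid (PAA) degradation pathway in prokaryotic
    genomes. Resolves representative protein domain architectures from
    overlapping HMM hits by weighted-interval-scheduling, discriminates
    phenylacetate-CoA ligases (PAL, PaaK) from related ANL-superfamily
    enzymes by motif scanning with exact position-weight-matrix p-values
    and QFAST combined p-values, classifies PAL gene neighbourhoods into
    pathway configurations (full pathway, upper pathway, epoxidation
    module, partial multicomponent, other), and quantifies cophylogenetic
    congruence of the PaaA and PaaC epoxidase subunits with a Procrustean
    superimposition analysis, quantile residual banding, and categorical
    association statistics (bias-corrected Cramer's V, permutation
    independence test). A synthetic-data generator emulates every input so
    the whole chain is testable without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    ape,
    phangorn,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    rtracklayer,
    GenomicRanges,
    vegan,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
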