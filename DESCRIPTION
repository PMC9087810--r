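Package: neuropathNet
Title: Covariance Networks and Mediation Models for Regional Digital
    Histopathology
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds group-level correlation ("structural covariance")
    networks over gray-matter and white-matter percent-area-occupied
    pathology measurements from autopsy cohorts, compares edge weights
    between proteinopathy groups with the two-sample Fisher r-to-z test,
    relates weighted node strength to regional pathology burden, and tests
    causal mediation of anterior-to-posterior gray-matter pathology by
    white-matter pathology with a percentile-bootstrap indirect effect.
    Includes a seeded synthetic-cohort generator with block-structured
    correlations, region-level missingness, and planted mediation chains,
    so the full pipeline is testable without access to restricted autopsy
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    MASS,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
biocViews: Network, GraphAndNetwork, Regression, Pathology
RoxygenNote: 7.3.3
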