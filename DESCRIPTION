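Package: sentitract
Title: Neighborhood Sentiment Scoring and Spatial Regression of Areal Health Outcomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for lexicon-based (hedonometer) sentiment scoring of geolocated
    short texts aggregated to areal units such as census tracts, word-shift
    decomposition of happiness differences between corpora, exploratory spatial
    data analysis (queen/rook contiguity weights, global Moran's I with
    permutation inference, LISA cluster classification), and spatial regression
    of unit-level health outcomes on sentiment and covariates via OLS, Lagrange
    multiplier diagnostics, and the generalized spatial two-stage least squares
    (GS2SLS) estimator of the SARAR model. Includes a fully seeded synthetic-data
    generator (lattice geographies, spatially autocorrelated covariates,
    SARAR-generated outcomes, and message corpora with controllable dialect
    confounding) so every stage of the pipeline can be exercised and validated
    without restricted social-media or survey data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    pracma,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
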