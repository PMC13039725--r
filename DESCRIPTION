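Package: bioclimfutures
Title: Projecting Community Turnover and Extinction Debt Under Climate
    and Land-Use Scenarios
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for projecting biodiversity futures from community
    incidence data. Fits generalised dissimilarity models (monotone
    I-spline transforms of environmental predictors with a negative
    exponential link and non-negative coefficients) to weighted site-pair
    Jaccard dissimilarities, projects them under climate scenarios to map
    compositional change and disappearing or novel bioclimates, combines
    land-use projections with Biodiversity Intactness Index coefficients
    into habitat-condition maps, and translates both into species heading
    for extinction through the species-area relationship. Includes a
    synthetic-landscape generator with known ground truth (niche-driven
    community turnover, smooth climate shifts, Markov land-use change,
    and multi-study abundance tables) so every estimator can be scored
    against the truth that produced its inputs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    pracma,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
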