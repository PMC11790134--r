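Package: soilcap
Title: Soil Heavy-Metal Pollution Capacity, Source Apportionment and
    Pollution-Area Mapping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Assessment of soil heavy-metal(loid) pollution from stratified
    soil surveys: environmental pollution capacity (Pi), contamination factor,
    Hakanson ecological risk and Nemerow indices with risk classification;
    positive matrix factorization (PMF) receptor modelling with
    measurement-uncertainty weighting and multistart diagnostics;
    self-organizing-map clustering with Davies-Bouldin model selection;
    inverse-distance and ordinary-kriging interpolation including a
    variogram-resampling ensemble predictor in the spirit of empirical
    Bayesian kriging; and contaminated-area delineation comparing site
    fractions with interpolated-surface fractions. Includes a calibrated
    synthetic soil-survey generator so the full pipeline runs and is testable
    without restricted survey data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    S4Vectors,
    SummarizedExperiment,
    MASS,
    car,
    nortest,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    readxl,
    clue,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
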