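Package: agriscape
Title: Synthetic Agricultural Landscape Generation, Metrics and Calibration
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generates synthetic agricultural landscapes with a three-step
    workflow: a "potential space" mask for arable land is synthesised from
    fractal gradient (Perlin) noise or derived from a real land-cover map via
    a cell-wise logistic suitability model with majority-vote smoothing;
    discrete fields are then tessellated into that space with either a
    segment-wise place-and-conquer algorithm or a modified dead-leaves
    algorithm; finally fields are enriched with farmer and crop identities.
    Roads and rivers can be carved out of the potential space with least-cost
    paths over a slope surface. The package computes FRAGSTATS-style
    landscape metrics (number of patches, patch area, largest patch index,
    contagion, edge density, Euclidean nearest neighbour, shape, landscape
    shape index, fractal dimension, perimeter-area ratio) and calibrates
    generator parameters against a reference metric profile with an elitist
    genetic algorithm, so that any number of landscapes statistically
    equivalent to a reference map can be produced. All stochastic steps are
    seeded and fully reproducible.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    igraph,
    jsonlite,
    yaml,
    lhs,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
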