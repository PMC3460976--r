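Package: forestspat
Title: Spatial Point-Pattern Analysis of Mapped Forest Census Plots
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for stem-mapped forest census plots:
    life-stage classification from diameter distributions, topographic
    habitat classification of 20 m quadrats (elevation, slope, convexity),
    torus-translation and random-map tests of species-habitat association,
    uni- and bivariate pair-correlation functions with exact disc-rectangle
    edge correction, heterogeneous Poisson null models built from
    Epanechnikov kernel intensity surfaces, Monte Carlo simulation
    envelopes and goodness-of-fit rank tests, aggregation of pairwise
    association results across life stages, and a synthetic multispecies
    community generator with known ground truth for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
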