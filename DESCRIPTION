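Package: biintact
Title: Annual Biodiversity Intactness Index from Assemblage Data and
    Anthropogenic Pressure Layers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates annual maps and regional trends of the Biodiversity
    Intactness Index (BII) from site-by-species assemblage surveys and gridded
    anthropogenic pressure layers. Fits Gaussian linear mixed-effects models of
    square-root rescaled total abundance and of logit-transformed asymmetric
    abundance-based Jaccard compositional similarity against land use, use
    intensity, human population density and road density; provides AIC random
    slope selection, backward stepwise simplification, bootstrap and
    within-study permutation inference; builds annual pressure stacks
    (population interpolation, two-scale road density, forest-cover
    harmonisation, intensity allocation, covariate capping); projects both
    models relative to a minimally-used primary-vegetation baseline and
    multiplies them into BII rasters; and aggregates BII to regions with log
    response ratio trends, Wilcoxon signed-rank tests and GDP association
    models. A seeded synthetic-world generator with known ground truth stands
    in for the assemblage database and global layers so that every stage is
    testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    lme4,
    nlme,
    car,
    ape,
    geosphere,
    jsonlite,
    stats,
    graphics,
    utils
Suggests:
    testthat (>= 3.0.0),
    tiff
Config/testthat/edition: 3
RoxygenNote: 7.3.3
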