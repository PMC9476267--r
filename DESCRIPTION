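Package: grazemix
Title: Grazing-Personality Behaviours from GPS Tracking and Mixed-Model
    Genotype Association
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds per-animal grazing-personality behaviours from GPS
    relocations and a digital elevation model, and tests their association
    with candidate-gene genotypes using linear and generalised linear mixed
    models. Covers trajectory construction with speed/turning-angle outlier
    filtering, terrain annotation (elevation, slope, aspect) from raster
    grids, eleven daily movement and terrain-use metrics (distances, elevation
    gain, relative elevation, minimum-convex-polygon home range, movement
    tortuosity), day- and animal-level quality filters, random-structure model
    selection by information criteria, Satterthwaite tests, estimated marginal
    means with back-transformation, Benjamini-Hochberg post-hoc comparisons
    with compact letter displays, and a synthetic-herd simulator with known
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    emmeans,
    generics,
    ggplot2,
    jsonlite,
    lme4,
    lmerTest,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    xml2,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
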