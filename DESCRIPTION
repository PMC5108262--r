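Package: prwr
Title: Predicted Rarity-Weighted Richness for Conservation Site
    Prioritization
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to prioritize sites for species representation when
    species inventories exist for only a fraction of a planning area.
    Computes rarity-weighted richness (RWR) from binary site-by-species
    incidence data, reduces an environmental covariate pool to one
    representative variable per significant principal component, fits a
    random-forest model of RWR on an inventoried subset of sites,
    predicts rarity-weighted richness (PRWR) landscape-wide, and
    quantifies surrogate efficiency with the Species Accumulation Index
    against optimal (maximum-coverage) and random (hypergeometric
    expectation) baselines.  Includes a virtual-landscape simulator with
    Gaussian species niches and tunable environmental determinism for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    randomForest,
    ggplot2,
    rlang
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Roxygen: list(markdown = TRUE)
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'occurrence.R'
    'envSelection.R'
    'surrogateModel.R'
    'rwr.R'
    'representation.R'
    'experiment.R'
    'prwr-package.R'
    'simulate.R'
    'utils.R'
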