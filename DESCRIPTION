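Package: nichebreadth
Title: Climatic Niche Breadth Decomposition and Phylogenetic Regression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for macroecological analyses of climatic niche breadth
    from georeferenced occurrence records with joined bioclimatic values.
    Provides occurrence quality control (coordinate deduplication, reverse
    jackknife and 1.5 IQR climatic outlier screens), species- and
    region-level temperature and precipitation niche breadth and position
    statistics, a decomposition of species niche breadth into within- and
    among-locality components, phylogenetic generalized least squares
    regression under Pagel's lambda model with maximum-likelihood lambda
    estimation, a synthetic-data generator with known ground truth for
    validation, and a reproducible end-to-end analysis pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    nlme,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
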