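Package: divtriad
Title: Linking On-Farm, Market and Dietary Diversity with
    Instrumental-Variable GMM
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for studying how the diversity of plant species a rural
    household grows or collects (on-farm diversity), the variety of foods a
    mother purchases (market diversity) and her dietary diversity relate to
    each other.  The package scores 24-hour recalls into the ten-group
    women's dietary diversity score and the Minimum Dietary Diversity-Women
    indicator, counts purchased-food and species diversity from 7-day food
    and species inventories, builds an asset-based socioeconomic index by
    factor analysis, and estimates a three-equation simultaneous system with
    exponential (Poisson-type) and linear mean functions by two-step
    generalized method of moments with instrumental variables and
    household-clustered sandwich standard errors.  Endogeneity and
    instrument diagnostics (Durbin-Wu-Hausman, Sargan-Hansen, first-stage F)
    and a synthetic household-survey generator for validation are included.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    tools,
    utils,
    jsonlite,
    yaml,
    sandwich
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
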