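Package: geomicrobe
Title: Microbial Source Attribution by Penalized Geolocation Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for predicting the geographic origin of microbiome
    samples from taxonomic abundance profiles. Implements cumulative sum
    scaling (CSS) normalization of taxa-by-sample count tables, multi-task
    Lasso regression of latitude and longitude, city-weighted multinomial
    classification and down-sampled random forests, nested 10-fold and
    leave-one-city-out cross-validation designs, and an open-set detector
    that flags samples from never-sampled origins via the Simpson index of
    their class-probability vectors. A seeded generator of city-structured
    synthetic count data with planted latitudinal gradients supports
    end-to-end testing without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    glmnet,
    randomForest,
    vegan,
    ape,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
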