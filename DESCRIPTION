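Package: chemotyper
Title: Chemotype Discovery and Chemomarker Screening for Non-Targeted
    Metabolomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for leaf chemotyping from non-targeted
    metabolomics feature tables: QC-anchored signal-drift correction with
    algorithm selection (random forest, LOESS, support vector regression),
    k-nearest-neighbour imputation, self-organizing-map and K-means
    chemotype discovery adjudicated by random-forest cross-validation and
    the gap statistic, one-vs-rest OPLS-DA with permutation validation,
    four-criterion chemomarker screening (VIP, t-test, fold change, mean
    decrease accuracy), and chemomarker-to-morphology linkage via weighted
    metabolite co-expression modules, random-forest importance and LASSO
    predictability. A synthetic-data generator plants known chemotypes,
    markers, injection-order drift and trait couplings so every stage is
    verifiable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    pROC,
    purrr,
    randomForest,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    cluster,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
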