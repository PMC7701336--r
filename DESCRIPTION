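Package: cardioclust
Title: Unsupervised Discovery of Rare Pathological Clusters in Cardiac
    Shape and Motion Features
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for unsupervised detection of rare pathological
    subpopulations (right-ventricular abnormality, dilated cardiomyopathy)
    in population cohorts described by nine image-derived cardiac shape and
    motion features. Provides a synthetic cohort simulator with known
    subgroup truth, redundancy screening of feature pairs by Pearson
    correlation and the maximal information coefficient (MIC),
    expectation-maximization fitting of Gaussian mixture models with tied,
    diagonal and full covariance structures, BIC-based model selection with
    a prevalence gate on small-cluster candidates, an ACDC-style threshold
    rule engine that labels clusters as pathological, and a validation
    battery (PCA projection of cases and cluster centers, pairwise Welch and
    Mann-Whitney tests across large clusters, and Huber robust regression
    against a reference measurement channel).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    S4Vectors,
    SummarizedExperiment,
    MASS,
    jsonlite,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    mclust,
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: Clustering, DimensionReduction, StatisticalMethod
RoxygenNote: 7.3.3
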