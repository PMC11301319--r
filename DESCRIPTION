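Package: plastmap
Title: Functional Mapping of Transgenerational Phenotypic Plasticity QTLs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for dissecting the genetic architecture of developmental
    phenotypic plasticity in recombinant inbred line (RIL) panels grown under
    a reciprocal two-generation design. The package simulates RIL genotypes
    and six-treatment leaf-number growth trajectories, builds time-course
    plasticity traits as differences of paired trajectories, maps plasticity
    QTLs with a composite functional-mapping likelihood (logistic genotype
    mean curves, summed first-order structured-antedependence covariance,
    permutation-calibrated likelihood-ratio test), and classifies detected
    QTLs into modules by mixture-model clustering of their time-varying
    genetic effect curves with BIC model selection.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils,
    yaml,
    vcfR,
    jsonlite,
    withr
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
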