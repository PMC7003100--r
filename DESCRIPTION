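Package: namqg
Title: Quantitative Genetic Dissection of Nested Association Mapping Populations
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Simulation and analysis toolkit for nested association mapping
    (NAM) populations of recombinant inbred lines. Provides a seeded synthetic
    NAM generator (founders, Haldane meiosis, multi-environment augmented field
    trials), marker quality control and naive imputation, spatially adjusted
    genetic-merit estimation with EM-REML variance components and deregressed
    BLUPs, additive and additive-by-additive (G2A) genomic kernels, multi-kernel
    variance decomposition, bivariate GBLUP genetic correlations and indirect
    selection efficiency, a tri-method genome scan (family-nested mixed-model
    likelihood ratios, BayesCpi model frequencies, random-forest importance
    with permutation thresholds), and genomic prediction with GBLUP and BayesB
    under within-family, across-family and leave-family-out cross-validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics, ranger, jsonlite, yaml, Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), withr, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
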