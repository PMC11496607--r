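Package: ngnn
Title: Solvent-Aware Graph Neural Networks for Molecular Property Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Multiscale featurization of solute-solvent systems and a
    natural-growth message-passing neural network for predicting
    physicochemical properties (solubility, absorption and emission
    wavelengths, quantum yields) of molecules in solution. Atoms carry
    inherent physical constants and one-hot environmental features; solvents
    enter through a 66-descriptor vector (E-state, VSA, topological,
    connectivity families) broadcast onto solute atoms and through
    solvatochromic polarity parameters (Et(30) and the Catalan set) injected
    into bond features. Two dissolved molecular graphs are message-passed,
    read out with a set2set operator and decoded to a scalar property.
    Includes dataset splitting, Adam training with early stopping,
    MAE/RMSE/MRE/R2 evaluation, a multi-run protocol, and a deterministic
    toy-data generator with closed-form target rules for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    ChemmineR,
    ChemmineOB,
    igraph,
    tibble,
    dplyr,
    purrr,
    readr,
    rlang,
    jsonlite,
    ggplot2,
    generics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
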