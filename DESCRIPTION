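Package: pkagraph
Title: Chemistry-Guided Graph Attention Models for Microscopic pKa Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts microscopic pKa values of small organic acids and bases
    with a masked multi-head graph-attention (GATv2) regressor built on
    chemistry-principle features: atomic electronegativity, hardness and
    diameter, hybridization, ring size and hydrogen counts, plus bond order,
    a revised conjugation indicator that distinguishes delocalized conjugate
    bases (e.g. carboxylates) from their neutral acids, and bond polarization
    directed away from the ionization center. Includes rule-based detection of
    ionizable sites, an iterative protocol that maps a molecule's full
    ionization profile and its dominant protonation state at a given pH,
    similarity-capped (Tanimoto) cluster splitting, graph-randomization data
    augmentation, a synthetic library generator with a distance-attenuated
    inductive-effect ground truth, and fingerprint/descriptor baseline
    regressors (random forest, gradient-boosted trees).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    rlang,
    readr,
    withr,
    ggplot2,
    generics,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    randomForest,
    xgboost,
    ChemmineR,
    ChemmineOB,
    optparse,
    knitr
Config/testthat/edition: 3
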