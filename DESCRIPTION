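Package: cytosig
Title: Cytokine Signature Discovery and Immunometabolic Readout Analysis
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Multivariate discovery of cytokine signatures from multiplex
    immunoassay (Luminex-style) data, together with the downstream readouts
    used to characterize their effect on neuronal metabolism. Implements
    automated plate-reading cleanup (bead-count filtering, technical-triplicate
    outlier resolution, detection-limit censoring, sparse-analyte removal),
    NIPALS partial least squares regression and discriminant analysis with
    repeated random-subsampling cross-validation, permutation significance,
    post-hoc orthogonalization and VIP-based signature extraction, nCounter-style
    count normalization and differential-expression filtering, Mito Stress Test
    oxygen-consumption metric extraction, and interaction-network component
    pruning. Seeded synthetic-data generators with planted ground truth make
    every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    mixOmics,
    readr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
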