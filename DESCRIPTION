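Package: corticonorm
Title: Normative Modelling of Neonatal Cortical Microstructure and Morphology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Gaussian-process normative modelling of parcel-wise cortical
    features in term and preterm neonates. Simulates term/preterm cohorts
    with known ground truth (Voronoi-style spherical parcellation, metric-
    and region-specific age trajectories, prematurity-graded group effects,
    sparse individual extreme deviations), fits per-parcel per-metric
    Gaussian-process models of typical development (RBF + linear + white
    noise kernels, marginal-likelihood optimisation), derives individual
    Z-scores, extreme-deviation overlap maps and whole-cortex atypicality
    indices, runs Freedman-Lane max-statistic permutation inference with
    family-wise error correction across parcels, modalities and contrasts,
    predicts postmenstrual age with random-forest regression and
    error-in-variables bias correction, and relates deviations to age at
    birth and developmental outcome with rank-based tests under FDR control.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    generics,
    ranger,
    jsonlite,
    yaml,
    readr,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
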