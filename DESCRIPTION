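Package: latline
Title: Lateral Line Morphology and Collective Behaviour in Fish Shoals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for linking cranial lateral-line morphology to collective
    behaviour in shoaling fish. Computes per-trial group-cohesion metrics
    (nearest neighbour, group radius, upstream and field-of-flow nearest
    neighbour) from tracked trajectories; converts digitized canal-pore
    outlines (TPS dialect) into equidistant semilandmarks and polygon pore
    areas with Procrustes/PCA and digitization-error ANOVA; fits
    negative-binomial random-intercept mixed models by adaptive
    Gauss-Hermite quadrature with AICc-based model selection and
    support-table coding; and simulates a desk-scale artificial lateral-line
    canal sensor behind a vortex-shedding cylinder with a lattice-Boltzmann
    wake solver and a lumped-parameter pore model. Includes synthetic-data
    generators (designs, morphology, pore outlines, behaviour responses and
    trajectories) with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    grDevices,
    pracma,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    glmmTMB,
    MASS,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
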