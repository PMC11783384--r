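Package: dyaddm
Title: Dyadic-Training Social Influence on Visual Categorization with
    Hierarchical Drift-Diffusion Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis pipeline for two-phase dyadic
    training experiments on visual categorization of Glass patterns.
    Provides declarative experiment designs, a coordinate-level Glass
    pattern dipole generator, a synthetic cohort generator built on
    drift-diffusion observers paired with Boltzmann-policy partners,
    psychometric (Boltzmann sigmoid) boundary estimation, a ten-model
    hierarchical Bayesian drift-diffusion analysis with drift-rate and
    starting-point regressions on personal and social information and
    DIC model comparison, model validation by posterior prediction,
    parameter recovery, partner-boundary cross-validation and PSE-shift
    parameter grids, and study-level behavioral indices
    (switch-probability tables, confidence dynamics, metacognitive
    sensitivity, social susceptibility, bias indices, bootstrap
    mediation).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    tools,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
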