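Package: udpharm
Title: Uniform-Design Herb-Formula Effect and Mediation Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for inferring dose-effect and mediation structure of
    multi-herb formulations studied under uniform experimental designs.
    Implements good-lattice-point uniform design construction with centered
    L2-discrepancy generator selection, body-surface-area dose conversion,
    macroscopic ulcer-index scoring, entropy-weight-method composite efficacy
    indices, stepwise polynomial regression analysis (LASSO screening followed
    by bidirectional stepwise AIC refinement over linear, quadratic and
    interaction dose terms), NIPALS partial least squares regression with
    VIP-based mediator screening, piecewise structural equation modelling with
    d-separation basis sets and Fisher's C adequacy testing, and Spearman
    correlation matrices. A synthetic-study generator with known sparse dose
    effects and mediation paths supports end-to-end parameter-recovery
    validation of the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    glmnet,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mixOmics,
    withr
Config/testthat/edition: 3
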