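Package: ltagmm
Title: Latent Transition Analysis with Growth-Mixture Measurement
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Two-stage latent transition analysis in which the measurement
    model at each stage is a finite mixture of linear latent growth curves
    (a piecewise growth mixture model), estimated by multi-start EM with
    full-information handling of missing indicators. Implements the 3-step
    maximum-likelihood transition model with classification-error
    correction and covariate effects on class membership and on the
    transition, model-selection indices (BIC, sample-size-adjusted BIC,
    relative entropy), multiple imputation with Rubin-rules pooling, and a
    synthetic longitudinal panel generator emulating a large early-reading
    cohort so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, MASS, jsonlite
Suggests: testthat (>= 3.0.0), withr, mclust, yaml, optparse
Config/testthat/edition: 3
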