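Package: chdi
Title: Composite Hospital Performance Scoring with Principal Components and Entropy Weights
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Builds composite hospital-performance indices from a hospitals-by-indicators
    table. Indicators are grouped into three domains (research and development, academic
    reputation, quality and safety); each domain is reduced with principal component
    analysis, or categorical principal component analysis via optimal-scaling alternating
    least squares when indicators are ordinal or nominal, after Kaiser-Meyer-Olkin or
    Cronbach alpha suitability checks and an exhaustive indicator-subset search. Retained
    component scores are logit-transformed, combined within domains by the entropy weight
    method, aggregated across domains with configurable weights, and min-max rescaled into
    a ranked development index. A latent-factor simulator generates realistic synthetic
    hospital tables for testing and calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, yaml
Suggests: testthat (>= 3.0.0), jsonlite, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
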