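Package: upfsurvey
Title: Ultra-Processed Food Energy Contribution from Complex-Survey Dietary Recalls
Version: 0.1.0
Authors@R: person("Analysis", "Engineering", email = "dev@example.org", role = c("aut", "cre"))
Description: A tested pipeline for estimating the energy contribution of
    ultra-processed foods (Nova group 4) in young children from 24-hour
    dietary recalls collected under multistage stratified survey designs.
    Provides a rule engine for Nova food-processing classification, per-child
    energy accounting and the E4RZ energy-share statistic, the MAAT/POCT/MRAT
    indicator set with Taylor-linearization variance estimation and a Rao-Wu
    rescaling bootstrap oracle, a design-weighted two-part (binomial +
    sqrt-normal) covariate model with cluster-robust sandwich standard
    errors, and a synthetic survey generator with known ground truth so the
    whole pipeline is testable without microdata downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    MASS,
    optparse
Config/testthat/edition: 3
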