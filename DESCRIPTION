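Package: twinmediate
Title: Genetically Informed Mediation Analysis for Twin Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Structural equation modelling for twin-pair data with a focus on
    causal mediation. Provides a reticular-action-model (RAM) path engine with
    multi-group full-information maximum likelihood for twin pairs, univariate
    and bivariate ACE variance decomposition, phenotypic mediation models with
    family-clustered inference, and Mendelian Randomization-Direction of
    Causation (MR-DoC) mediation models that use a polygenic score as a
    genetic instrument. A seeded synthetic twin-cohort generator emulates the
    pair structure, ordinal item measurement, latent mediator factors and
    polygenic-score instrument of a population twin register so that every
    analysis stage can be exercised and validated without restricted data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    sandwich,
    lmtest,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
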