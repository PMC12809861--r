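Package: twinace
Title: Bivariate Twin and Sibling ACE Liability-Threshold Models for
    Endophenotype Validation
Version: 0.1.0
Authors@R:
    person("twinace", "developers", email = "twinace@example.org",
           role = c("aut", "cre"))
Description: Joint full-information maximum-likelihood modelling of a
    continuous neurocognitive trait and a binary diagnostic phenotype in
    monozygotic and dizygotic twin and sibling pairs. Implements the
    bivariate ACE liability-threshold model with fixed-parameter
    ascertainment correction (disease-side variance components and
    prevalence threshold pinned at published population values),
    constrained saturated correlation models, profile-likelihood
    confidence intervals and likelihood-ratio tests, decomposition of the
    phenotypic correlation into additive-genetic, shared- and
    unique-environment parts, a four-criterion endophenotype decision
    rule, and a synthetic twin-cohort generator with proband-type
    ascertainment schemes.
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
    optparse
Config/testthat/edition: 3
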