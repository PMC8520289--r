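Package: rdci
Title: Risk Difference Confidence Intervals and Non-Inferiority Concordance
Version: 0.1.0
Authors@R:
    person("rdci", "Maintainers", email = "rdci@example.org", role = c("aut", "cre"))
Description: Confidence intervals for the difference of two independent
    binomial proportions by five methods (Wald, Agresti-Caffo, Newcombe
    hybrid score, Miettinen-Nurminen score, and skewness-corrected
    asymptotic score), together with a trial-level pipeline for
    non-inferiority meta-research: per-comparison interval widths and
    conservatism, non-inferiority conclusions against study margins,
    five-method concordance across a sweep of margins, subgroup and
    subsampling sensitivity analyses, an exact coverage-probability
    engine, and a synthetic trial-cohort generator for fully
    self-contained testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
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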