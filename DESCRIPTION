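Package: platnash
Title: Simulation of Bayesian Phase 2b Platform Trials with Correlated
    Binary Co-Primary Endpoints
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Event-driven simulation of an exploratory phase 2b platform
    trial in non-alcoholic steatohepatitis (NASH) with two correlated binary
    co-primary endpoints (resolution of NASH without worsening of fibrosis,
    and one-stage fibrosis improvement without worsening of NASH). Provides
    four constructions of the bivariate Bernoulli outcome distribution
    (direct cell probabilities, sensitivity/specificity, phi correlation
    with attainability bounds, and dichotomized latent bivariate normal),
    conjugate Beta posterior machinery for the posterior probabilities that
    drive multi-level Bayesian efficacy and futility decision rules, a
    weekly trial engine with staggered cohort entry, block randomization,
    delayed outcome observation, interim analyses and concurrent control
    sharing, and aggregation of replicate results into operating
    characteristics (success probability, trial duration, enrollment,
    early-stopping probabilities) over scenario grids.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    mvtnorm,
    pracma,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
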