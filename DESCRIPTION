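Package: flybet
Title: Bet-Hedging and Adaptive Tracking Dynamics of Thermal Preference
    Variability in Drosophila
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Analysis of interindividual variability in Drosophila light and
    temperature preference and of whether that variability behaves like an
    adaptive bet-hedging strategy.  Provides synthetic generators for
    single-fly choice assays, overdispersion and repeatability statistics,
    beta-binomial fits, parent-offspring heritability estimation, a seasonal
    weather generator with autoregressive temperature deviations and
    autocorrelation-preserving cloud-cover surrogates, a temperature-dependent
    fly life-history model in both stochastic agent-based and
    infinite-population difference-equation form, equilibrium calibration of
    daily birth and death rates, and an experiment suite comparing bet-hedging
    against adaptive tracking across random seasons, climate offsets, season
    lengths, and phenotypic-variance regimes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
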