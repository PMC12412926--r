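Package: heatcco
Title: Time-Stratified Case-Crossover Analysis of Ambient Heat and Low
    Apgar Scores with Distributed-Lag Nonlinear Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating short-term effects of ambient temperature
    on rare perinatal outcomes with a bi-directional time-stratified
    case-crossover design. Builds municipality-level daily temperature and
    relative-humidity exposures (Tetens equation) from gridded hourly
    climate inputs, applies a low-risk birth-cohort exclusion cascade with
    full accounting, expands cases into matched day-of-week/month/year
    referent strata, constructs distributed-lag nonlinear crossbasis
    design matrices (natural cubic spline in temperature, linear or spline
    in lag), and fits conditional logistic and conditional quasi-Poisson
    models by Newton-Raphson to obtain odds ratios at population-weighted
    temperature percentiles. Includes a seeded synthetic generator of
    linked climate and birth-registry data with a known injected
    lag-response, so the whole pipeline is testable end to end without
    access to registry or reanalysis data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    splines,
    graphics,
    grDevices,
    jsonlite,
    yaml
Suggests:
    survival,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
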