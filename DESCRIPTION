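Package: nephcpue
Title: Standardization of Nephrops Trawl-Survey CPUE with Gamma Additive Models
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to turn haul-level Norway lobster (Nephrops norvegicus)
    trawl-survey catches into standardized biomass (kg/km^2) and density
    (N/km^2) abundance indices. Candidate Gamma generalized additive models
    with log link relate catch per unit effort to space (latitude, depth),
    environment (bottom temperature, salinity, oxygen saturation), time
    (year, week, time of day) and fishery-management regime; candidates are
    screened by variance-inflation-factor backward selection, compared by
    repeated k-fold cross-validation AIC distributions (Levene, ANOVA,
    Tukey), and pruned by a significance-frequency retention rule. The
    selected model predicts over an informed constant-area spatial grid
    carrying kriged environmental layers and management levels, and per-cell
    predictions are averaged into standardized index series with standard
    errors. A synthetic-survey generator reproduces the study design (two
    seasonal series, skewed near-zero-free CPUE, depths 100-270 m, staged
    fishery closures) so that every stage is testable without survey data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    mgcv,
    car,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml,
    MASS
Config/testthat/edition: 3
RoxygenNote: 7.3.3
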