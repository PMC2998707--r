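Package: distlag
Title: Distributed Lag Non-Linear Models via Cross-Basis Construction
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for modelling exposure-response relationships that are both
    non-linear and delayed in time, as commonly required in environmental
    time-series epidemiology (e.g. temperature and daily mortality counts).
    The package constructs one-dimensional bases for the predictor and lag
    spaces, combines them into a cross-basis design matrix suitable for any
    generalized linear model, extracts the fitted cross-basis coefficients
    and their covariance from the model, and computes lag-specific and
    overall (lag-summed) effects with standard errors relative to a
    reference exposure, on the linear-predictor or relative-risk scale.
    Includes overdispersion-adjusted information criteria (QAIC/QBIC) for
    model comparison and a synthetic-data generator producing overdispersed
    count series driven by a known exposure-lag-response surface, so the
    whole pipeline can be exercised and validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    splines,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
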