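Package: synthits
Title: Controlled Interrupted Time Series and Synthetic Control for
    Country-Year Rate Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quasi-experimental evaluation of population-level policies on
    annual health-outcome rate panels (events per 1000 women). Implements
    segmented regression for interrupted time series with level and trend
    change coefficients, an optional pre-intervention level corrector,
    common-shock terms, and iterative Prais-Winsten correction for lag-1
    autocorrelated errors, including a two-unit controlled comparison that
    subtracts a control country's changes from the treated country's.
    Implements the synthetic control method with donor weights on the
    probability simplex, data-driven search over contiguous groupings of
    pre-intervention years used as predictors, optimized predictor-importance
    weights, placebo-in-space permutation inference via post/pre mean squared
    prediction error ratios, in-time placebos, and iterative leave-one-out
    donor analyses. A deterministic synthetic panel generator reproduces the
    statistical structure these designs assume (shared secular trend with
    breaks, country offsets, a UK-specific 1996 level shock, lag-1
    autocorrelated noise) so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    quadprog,
    sandwich,
    stats,
    tools,
    utils,
    withr
Suggests:
    lmtest,
    nlme,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
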