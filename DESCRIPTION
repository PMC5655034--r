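Package: esmct
Title: Continuous-Time and Discrete-Time Autoregressive Modeling of
    Unequally Spaced Experience-Sampling Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the consequences of unequal measurement
    spacing in experience-sampling (ESM) time series. Provides exact
    simulation of the continuous-time first-order (vector) autoregressive
    process (CAR(1)/CVAR(1), i.e. the Ornstein-Uhlenbeck process) under
    signal-contingent beep schedules, translations between continuous-time
    drift matrices and interval-specific autoregression matrices via the
    matrix exponential, four interval-handling model implementations
    ranging from a naive equally-spaced AR model to the exact
    continuous-time model, maximum-likelihood and least-squares
    estimation with delta-method confidence intervals for the
    autocorrelation at any lag, and a simulation harness that summarizes
    estimation bias across measurement designs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Matrix,
    pracma,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
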