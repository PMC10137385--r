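Package: stickbalance
Title: Stochastic Delayed-Feedback Stick Balancing and Financial Stylized Facts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates human stick balancing as a stochastic delay
    differential equation for the vertical displacement angle under
    delayed, noisy proportional feedback. Provides regime classification
    (repeller, spiral node, spiral repeller), critical-gain thresholds by
    bisection with an analytic linear-stability oracle, and a
    stylized-facts pipeline comparing angular-velocity returns with
    financial return series: heavy-tailed distributions with q-Gaussian
    fits, absence of raw-return autocorrelation, and volatility
    clustering. Includes a GARCH(1,1) synthetic-return generator and
    readers for daily close-price CSV files.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
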