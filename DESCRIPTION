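Package: fracdrink
Title: Fractional-Order Compartmental Dynamics of Alcohol Addiction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for a seven-compartment alcohol-addiction transmission model
    under classical, Caputo fractional, and fractal-fractional (power-law)
    time derivatives. Provides the closed-form basic reproduction number and
    both equilibria, Lipschitz/Picard/Ulam-Hyers stability certificates, an
    Adams-Bashforth-Moulton predictor-corrector solver for Caputo systems, a
    two-point Lagrange product-integration solver for fractal-fractional
    systems, scenario runners for order sweeps and contact-rate reduction
    experiments, and synthetic-data generators for parameter-recovery studies.
    Results are returned as tibbles with broom-style tidiers and ggplot2
    autoplot methods.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
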