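Package: budcanal
Title: Competitive Auxin-Transport Canalization Between Two Axillary Buds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates and analyses a two-bud model of competitive auxin
    transport canalization in 2-node stem explants. Each bud's auxin efflux
    self-activates through a Hill-type positive feedback and inhibits the
    other bud through a shared stem sink; bud growth follows a second Hill
    function of efflux. The package integrates the system deterministically
    and stochastically (chemical-Langevin noise, drift-implicit
    Euler-Maruyama), enumerates and classifies steady states into six
    qualitative branching behaviors, maps behavior and stochastic outcome
    frequencies over the (v0, mu) parameter plane, extracts lag time,
    maximum growth rate, relative growth index and growth outcomes from bud
    length traces, places genotypes on the parameter plane under biological
    ordering constraints, and generates synthetic experimental-format
    datasets with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    readr,
    yaml,
    jsonlite,
    deSolve,
    stats,
    utils,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
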