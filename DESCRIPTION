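Package: pollinvade
Title: Simulating Pollinator Invasions in Plant-Pollinator Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for simulating the introduction of alien pollinator
    species into model plant-pollinator networks. Generates bipartite
    mutualistic networks with power-law degree heterogeneity and tunable
    nestedness, integrates a consumer-resource model of population
    dynamics with floral rewards and adaptive foraging, runs factorial
    in-silico introduction experiments across alien trait types,
    mortality scenarios and attachment rules, and analyses the resulting
    trial tables with regression trees and linear models to identify the
    species traits and network properties that predict invasion success
    and impacts on native species.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    purrr,
    Rcpp,
    rlang,
    rpart,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
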