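Package: melonopt
Title: Multi-Objective Cultivation Strategy Analysis for Hydroponic Netted Melon
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing factorial cultivation trials of hydroponic
    netted melon (Cucumis melo L.) across cultivar, substrate volume and
    planting density. Implements soluble-solids (Brix) and netting-panel fruit
    grading, min-max composite quality scoring, grade-dependent revenue, cost
    and return-on-investment economics, irrigation water productivity, and
    Pareto-frontier identification of non-dominated treatment combinations.
    Includes a calibrated synthetic generator for randomized complete block
    trial data, balanced three-way ANOVA with Tukey HSD compact letter
    displays, and plot-ready performance and correlation matrices.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
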