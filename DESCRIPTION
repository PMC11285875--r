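Package: coralcarb
Title: Carbon Budgets for Coralline Algal Calcification from Dual-Radioisotope Incubations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.com",
           role = c("aut", "cre"))
Description: Analysis pipeline for dual-radioisotope (45Ca + 14C) vial
    incubations of calcifying red algae. Converts scintillation activities
    into calcification, organic-fixation and CO2-release rates via specific
    activities, with magnesium adjustment and direct-deposition blank
    correction; estimates the organismal ratio of released CO2 to
    precipitated carbon; solves the seawater CO2 system and evaluates the
    Frankignoulle buffered-release ratio psi with a finite-difference
    oracle; partitions the organismal carbon budget among terminal sinks
    with Monte-Carlo uncertainty propagation; and provides tie-corrected
    Kruskal-Wallis, Dunn-Sidak and Pearson inference. A forward simulator
    of the incubation design makes the whole pipeline testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
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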