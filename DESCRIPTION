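Package: myddosome
Title: Kinetic Modeling of LPS/TLR4 Signaling Complex Assembly
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mass-action kinetic models of the assembly of LPS-induced TLR4
    signaling complexes (the Myddosome and a TIRAP-independent MyD88 activation
    complex), reconstructed as reaction networks from their published rate
    tables. Provides stiff ODE simulation of complex assembly time courses,
    pulldown-style observables matching SWATH-MS complex stoichiometry data,
    R-squared based global parameter fitting with a seed-reproducible
    differential-evolution optimizer, component distribution and stoichiometry
    analyses (dose-response scans, MyD88:TIRAP higher-order assembly ratios,
    phase classification), and a synthetic stoichiometry time-course generator
    with known ground truth for parameter-recovery and model-comparison
    experiments.
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
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
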