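Package: copred
Title: Dual-Predation Dynamics of Bacteria Preyed on by Bdellovibrio and
    Bacteriophage, with ABC-SMC Model Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Deterministic ordinary-differential-equation models of a bacterial
    prey population under simultaneous predation by the predatory bacterium
    Bdellovibrio bacteriovorus and a lytic bacteriophage, including prey
    subpopulations with genetic phage resistance and transient (plastic)
    resistance to Bdellovibrio. Provides a synthetic-data generator emulating
    48-hour predation-kinetics experiments (triplicate plate counts, detection
    limit, four culture conditions), an approximate Bayesian computation
    sequential Monte Carlo (ABC-SMC) engine for joint model selection and
    parameter inference, hierarchical model-competition pipelines, typical
    parameter-set extraction by principal component analysis, and
    initial-density sweeps. All user-facing functions take and return tidy
    data frames.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
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
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
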