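Package: hhreduce
Title: Steady-State Reduction of Order for Hodgkin-Huxley Cell Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for profiling relaxation time scales of Hodgkin-Huxley
    gating variables and reducing the order of conductance-based cell models
    by quasi-steady-state substitution, demonstrated on a uterine smooth
    muscle cell model. Provides the gating-variable framework (steady-state
    curves, voltage-dependent time constants, closed-form relaxation), the
    BK, T-type, L-type and fast Na+ channel submodels, voltage-scan (I-V)
    comparison of full-ODE versus steady-state gating, a configurable
    whole-cell simulator with per-variable ODE/SS mode switching, and a
    reduction toolkit that ranks conductances, flags steady-state candidates
    by time scale, and quantifies the fidelity of reduced model variants.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    tibble,
    dplyr,
    purrr,
    tidyr,
    ggplot2,
    readr,
    jsonlite,
    yaml,
    rlang,
    generics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
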