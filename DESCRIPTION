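Package: wardsim
Title: Stochastic Nursing-Home Simulation and Ethical Compliance
    Quantification for Assistive-Technology Policies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Discrete-time stochastic multi-agent simulation of a nursing
    home ward with disoriented residents, nurses, and a smart-watch
    assistive device that detects disorientation, issues orientation cues,
    and escalates to a nurse after a configurable number of failed cues.
    Simulation runs produce reproducible run protocols (per-tick state
    tables plus event logs) which an Ethical Compliance Quantification
    (ECQ) layer converts into numerical scores on ethical value dimensions
    (safety, fairness, efficiency), enabling Monte-Carlo comparison of
    assistive policies with paired seeds, trajectory maps, and per-policy
    score box plots.
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
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    igraph,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
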