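Package: ceimerge
Title: Communication-Enabled Interaction Model of Dyadic Merging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates pairs of human drivers resolving a symmetric merging
    conflict with the Communication-Enabled Interaction (CEI) model: each
    driver keeps a deterministic constant-acceleration plan, perceives the
    other vehicle's velocity through noisy evidence accumulation, maintains a
    two-component Gaussian-mixture belief over the other vehicle's future
    positions, and replans only when the perceived collision probability
    crosses personal dynamic risk thresholds. Includes the merging track and
    vehicle dynamics, batch simulation with reproducible seeding, behavioral
    metrics (merge gap, who merged first, velocity deviations), and a
    grid-search plus linear mixed-effects calibration pipeline with a
    synthetic-participant generator for parameter-recovery studies.
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
    lme4,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
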