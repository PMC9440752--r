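Package: robotandem
Title: Simulation and Analysis of Robot-Led Tandem-Running Homing Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for simulating and analysing homing assays in which ants
    are led to a new nest site by a robotic (gantry-mounted) tandem-run
    leader and then tracked on their return to the old nest.  Provides the
    arena coordinate frame and quadrant partition, constant-speed sinusoidal
    leader-path generation, a correlated-random-walk null simulator with an
    optional homing bias, trajectory statistics (path crossings with the
    leader's outward path, quadrant occupancy, censored return outcomes),
    right-censored survival inference (Kaplan-Meier, kernel-smoothed hazard,
    Cox proportional hazards with a colony-level log-normal frailty and
    likelihood-ratio comparison), Fisher exact conditional-MLE odds-ratio
    inference, Kruskal-Wallis tests with Holm-adjusted post hocs, and a
    synthetic cohort generator emulating the assay's treatment structure.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
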