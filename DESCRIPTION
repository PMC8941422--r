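Package: instdyn
Title: Coupled Dynamics of Behavioural Diffusion and Group-Level Institutions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the coevolution of a group-beneficial behaviour and the
    group-level institutions that promote it, in a population partitioned into
    many groups. Within each group the behaviour spreads by an SIS-style
    contagion whose rate is scaled by the group's discrete institutional
    strength; a global diffusion field couples groups together; and groups copy
    the institutional strategies of fitter groups, paying a per-level cost and
    gaining a per-adopter benefit. The mean-field master equations are
    integrated with a fixed-step fourth-order scheme; an exact event-driven
    (Gillespie) simulation of a finite ensemble of groups serves as a
    stochastic cross-check. Experiment drivers sweep parameters to steady
    state and detect collapse thresholds, source-sink and institutional
    free-riding effects, institutional localization, and bistability.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
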