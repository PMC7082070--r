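Package: beaconr
Title: Parse and Simulate Beacon Calculus Models of Biological Systems
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: The Beacon Calculus is a stochastic process algebra for modelling
    interacting biological components. Processes carry numeric parameters,
    perform rated actions combined by prefix, choice and parallel composition,
    and communicate either synchronously over channels (handshakes) or
    asynchronously through persistent, globally visible signals (beacons).
    'beaconr' parses models written in the bcs plain-text dialect, simulates
    them exactly with a Gillespie-type stochastic simulation algorithm over the
    induced continuous-time Markov chain, and returns tidy event logs. The
    package ships programmatic generators for reference models of DNA
    replication origin firing, the E. coli Ada-mediated DNA methylation damage
    response in a growing cell population, and multisite receptor
    phosphorylation ultrasensitivity, together with figure-level summary
    statistics (replication timing profiles, per-cell molecule traces,
    dose-response curves) and an explicit CTMC state-space expander used as a
    simulation oracle.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
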