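Package: hectsim
Title: Simulation of Bayesian Adaptive and Platform Clinical Trials
Version: 0.1.0
Authors@R:
    person("hectsim", "maintainers", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulates single and repeated Bayesian adaptive clinical trials
    with binary or continuous outcomes: early stopping for superiority,
    futility-based arm dropping (posterior probability of being best, or
    certainty that the effect is below a minimally clinically important
    margin), response-adaptive randomization with burn-in, and platform
    designs that admit queued treatment arms when an arm is dropped or the
    trial continues perpetually. Operating characteristics (type I error,
    power, expected sample size, cost and duration) are estimated by Monte
    Carlo over many simulated trials and compared against a conventional
    fixed-sample 1:1 design. A conventional normal-approximation sample-size
    calculator (two-arm and multi-arm with multiplicity adjustment) is
    included, along with a JSON scenario-configuration format and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
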