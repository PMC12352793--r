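Package: ehrgame
Title: Evolutionary Game Analysis of Hospital Co-Opetition over EHR Integration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the two-party evolutionary game between a superior and a
    subordinate hospital deciding whether to cooperate on electronic health
    record (EHR) integration inside a medical consortium. Builds the
    pure-strategy payoff table from revenue, cost, synergy and
    reward-punishment parameters, derives the two-population replicator
    dynamics, finds and classifies the rest points by the determinant and
    trace of the Jacobian, computes the saddle point and the quadrilateral
    basin-area statistic with its closed-form parameter sensitivities, and
    numerically integrates trajectories and single-parameter sweeps. A seeded
    scenario generator produces parameter sets constrained to each stability
    regime so the whole pipeline is testable without external data. Results
    are returned as tibbles with broom-style tidy() and glance() methods and
    ggplot2 autoplot() methods.
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
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
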