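Package: smili
Title: Agent-Based Simulation of Self-Governance in Small-Scale Fisheries
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Daily-resolution agent-based model of a small-scale fishery in
    which 100 heterogeneous fishers organize into patron-client relationships
    (a fishbuyer lending daily fishing capital against delivery of the catch)
    or fishing cooperatives (fixed membership, shared capital pot, collective
    trading), while harvesting a shared fish stock with logistic
    (Gordon-Schaefer) dynamics.  Trust is modelled as a fixed reliability
    trait plus a dynamic, relationship-scoped loyalty that grows on honest
    trades and erodes on cheating; organizations enter annually, go out of
    business when they run out of capital, loyalty or members, and the
    community-level outcome is the emergent dominance of one governance form.
    Includes a calibrated reference scenario, a validation ladder of
    increasingly complex presets, deterministic/stochastic/seasonal
    environmental regimes, and a replicated experiment-grid runner.  The
    production engine is written in C++ (Rcpp); a pure-R reference engine
    consuming the identical random-number stream is included for
    cross-validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    graphics,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
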