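Package: schellingRL
Title: Multi-Agent Reinforcement Learning on the Schelling Segregation Model
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: A two-population Schelling-style grid world in which agents learn
    where to move with per-type Deep Q-Networks. The toroidal lattice, the
    six-component reward structure (segregation, interdependence, vigilance,
    death, occlusion, stillness), experience replay with double Q-learning and
    soft target updates, and the analysis statistics (multiscale-entropy
    segregation, occupancy heatmaps, age-conditional probability matrices) are
    all implemented, together with deterministic fixtures and an experiment
    runner for intolerance/interdependence sweeps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml,
    zoo
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
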