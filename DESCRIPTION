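Package: quboyield
Title: QUBO Models for Chemical Reaction Yield Prediction and Condition
    Optimization
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for predicting chemical reaction yields and searching for
    optimal reaction conditions with quadratic unconstrained binary
    optimization (QUBO). Provides a gradient-fitted quadratic yield model
    over one-hot and fingerprint reaction encodings, a binary-coded
    least-squares model whose integer coefficients are found by annealing,
    a simulated annealer with an exact brute-force oracle for small
    instances, quadratic penalty constraints, conditional Q-matrix
    reduction for per-reaction inference, an active-learning loop with
    random, strategic and adaptive batch selection, evaluation metrics,
    and a synthetic high-throughput-experimentation data generator with
    planted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
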