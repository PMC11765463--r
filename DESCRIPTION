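Package: aifpomdp
Title: Active Inference Agents for Discrete State-Space POMDPs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building, simulating and fitting active inference
    agents defined on discrete state-space partially observable Markov
    decision processes (POMDPs). Provides multi-factor, multi-modality
    generative model construction (observation, transition, preference,
    state and habit priors), variational state inference by fixed-point
    iteration, expected-free-energy policy evaluation with precision-
    controlled action selection, Dirichlet concentration-parameter
    learning, a T-maze simulation environment, and per-subject Bayesian
    (MCMC) estimation of agent hyper-parameters from observation-action
    data, including parameter-recovery reporting and PSIS-LOO model
    comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
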