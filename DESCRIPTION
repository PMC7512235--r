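Package: penniesinfo
Title: Information Dynamics of Iterated Matching-Pennies Play
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation and information-theoretic analysis of iterated
    matching-pennies sessions. Provides the game's payoff and reward-gate
    logic, subject-side strategies (Tit-for-Tat, win-stay/lose-switch and its
    stochastic variant, softmax reinforcement learning, general Markov policy
    tables), the adaptive computer opponents that test for and exploit
    choice- and reward-history biases, a reproducible closed-loop session
    simulator with TSV serialization, plug-in estimators of entropy, mutual
    information, conditional mutual information and transfer entropy on small
    discrete alphabets, and a sliding-window trace pipeline: total and
    pairwise information traces, the signed higher-order statistic delta-I,
    exact decomposition identities implied by the reward gate, a two-step
    memory measure, time-shift surrogate baselines, and log-normal fits of
    trace distributions.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr,
    MASS
Config/testthat/edition: 3
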