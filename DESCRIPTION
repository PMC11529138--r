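Package: rlddm
Title: Reinforcement-Learning Drift Diffusion Modelling of the Probabilistic Selection Task
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the probabilistic selection task (three symbol pairs
    reinforced at 80/20, 70/30 and 60/40, criterion-based stopping), implements
    the reinforcement-learning drift diffusion model in which trial-wise drift
    rates are scaled differences of delta-rule Q-values and choices plus
    response times follow the Wiener first-passage-time distribution, and fits
    single- and dual-learning-rate variants by hierarchical Bayesian MCMC.
    Includes DIC model comparison, directional posterior contrasts with a
    posterior-odds Bayes factor, behavioural preprocessing (response-time
    outlier filtering, performance summaries, learning curves), and a
    synthetic two-condition study generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
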