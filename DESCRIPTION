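Package: devaltms
Title: Outcome-Devaluation TMS Experiments: Simulation, Learning Models, and
    Connectivity Embeddings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing, simulating, and analyzing two-day
    outcome-devaluation experiments with network-targeted transcranial
    magnetic stimulation (TMS). Provides deterministic generators for
    discrimination and choice-test schedules, a synthetic cohort simulator
    (behavior, pleasantness ratings, and resting-state functional
    connectivity), hierarchical Bayesian Rescorla-Wagner modeling of
    discrimination learning via JAGS, covariate-adjusted mixed-effects
    analyses of probe choices, array-level connectivity construction
    (multi-echo combination, framewise displacement, nuisance regression,
    ROI correlations), and a participant-conditioned variational autoencoder
    that quantifies stimulation-induced deviation of connectivity patterns
    in latent space.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    coda,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lme4,
    purrr,
    rjags,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    car,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
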