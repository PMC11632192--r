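Package: mwtbio
Title: EEG Biomarkers for the Maintenance of Wakefulness Test
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of Maintenance of Wakefulness Test (MWT)
    sessions for narcolepsy studies. Generates synthetic MWT studies with
    known log-linear latent sleepiness trajectories, hypnodensities,
    hypnograms, microsleep events and surrogate EEG; computes per-session
    biomarkers (sleep onset latency, microsleep rate and duration,
    hypnodensity-derived sleepiness scores, multitaper theta/alpha ratios,
    and log-linear trajectory slopes and intercepts); and fits the study's
    statistics: linear mixed-effects models with change-from-baseline
    contrasts, a prior-stabilized Bayesian mixed model with a WAIC/LOO
    hyperparameter sweep, and repeated-measures correlations.
License: MIT
Encoding: UTF-8
Imports:
    lme4,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
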