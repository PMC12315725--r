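Package: segbias
Title: Lifespan Resting-State Network Segregation and Valence Bias
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how resting-state functional brain network
    segregation changes across the lifespan and how it relates to valence
    bias, the tendency to judge emotionally ambiguous stimuli as positive.
    The package scores the two-alternative forced-choice valence bias task,
    converts realignment traces to filtered framewise displacement and
    applies motion censoring with contiguity, run-length and frame-budget
    rules, cleans ROI time series (detrending, nuisance regression,
    interpolation, band-pass filtering), builds Fisher-z connectivity
    matrices over a 300-ROI/14-network parcellation, computes within- and
    between-network connectivity and network segregation, and fits the
    lifespan statistical models: motion residualization, linear/quadratic
    age models with FDR correction, AIC backward elimination with forced
    covariates, interaction screening, simple slopes and Johnson-Neyman
    moderation intervals. A seeded synthetic-cohort generator with planted
    age and connectivity effects makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    signal,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
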