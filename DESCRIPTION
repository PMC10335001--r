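Package: slopediff
Title: Slopes Difference Tests and Monte Carlo Power Analysis for
    Longitudinal Cluster-Randomized Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Probes aptitude-by-treatment-by-time cross-level interactions in
    three-level longitudinal mixed models fitted to cluster-randomized trial
    data.  Provides the slopes difference test and simple-slope statistics on
    REML fits, a generative model for three-level longitudinal trial data, a
    seed-reproducible Monte Carlo engine that estimates power, convergence and
    singular-fit rates across a factorial grid of design conditions, and
    meta-analysis utilities (factorial ANOVA with eta-squared, Tukey HSD
    post-hoc comparisons, threshold percentage tables) for summarizing the
    simulation outcomes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    jsonlite,
    parallel,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
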