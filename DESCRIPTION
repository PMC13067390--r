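Package: dfcstates
Title: Sex Differences in Static and Dynamic Functional Connectivity States
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for resting-state functional-connectivity
    analysis of sex differences: static Fisher-z connectivity with graph
    measures of integration (global efficiency) and segregation (modularity),
    sliding-window dynamic connectivity clustered into two brain states
    (integrated/segregated) by cosine k-means, per-subject state dynamics
    (prevalence, mean dwell time, inter-transition interval, state
    variability), group comparison statistics (t-tests, Mann-Whitney U,
    Cohen's d, chi-square balance tests), and bootstrap mediation of
    behavioral sex differences by brain integration. Includes a synthetic
    cohort generator (Markov-switching multivariate Gaussian ROI signals with
    sex-dependent state occupancy, framewise-displacement series and
    behavioral variables with planted mediation structure) so the full
    pipeline is testable without restricted fMRI data.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    igraph,
    car,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
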