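Package: earlydisc
Title: Crowd-Sourced Scoring, Consensus Risk Groups, and Trial Enrichment
    for Early Treatment Discontinuation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for evaluating risk predictors of early treatment
    discontinuation in oncology trials and for quantifying their value in
    trial design.  Implements challenge-style leaderboard scoring of risk
    scores against a rare binary outcome (area under the precision-recall
    curve with a random-model null distribution, one-sided empirical
    p-values with Benjamini-Hochberg adjustment, and paired-bootstrap
    Bayes factors that delimit a statistically indistinguishable top set),
    cumulative lift-ratio analysis, rank-based consensus clustering of
    patients into concordant-high, concordant-low, and discordant risk
    groups with competing-risks cumulative incidence, a weighted-average
    ensemble of risk predictors with holdout-derived weights, and a
    simulation of balanced two-arm survival trials that screen out
    predicted early discontinuers to estimate sample-size requirements
    across hazard-ratio and screening-accuracy grids.  A synthetic cohort
    generator emulating a four-trial metastatic prostate cancer data
    structure makes every stage testable without access-controlled data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
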