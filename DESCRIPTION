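Package: drinkshift
Title: Meta-Analysis of Paired-Proportion Change Scores in Alcohol Use
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for synthesising self-reported changes in alcohol use
    across observational studies. Computes the paired-proportion change
    score (proportion of drinkers reporting increased use minus the
    proportion reporting decreased use) with its closed-form multinomial
    standard error, pools estimates with random-effects meta-analysis
    (REML or DerSimonian-Laird tau-squared), fits single-moderator
    meta-regressions with Bonferroni-corrected inference, provides
    heterogeneity statistics (Cochran's Q, I-squared), Egger's
    regression-based small-study-bias test, funnel-plot data, and
    leave-one-out sensitivity analysis. Includes study-table validation
    and preparation helpers (drinker-denominator reconstruction,
    starter/stopper folding, pandemic-period averaging, subset
    assembly), a study-level synthetic-data generator for simulation
    experiments, and a pipeline orchestrator producing a reproducible
    report bundle.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics, jsonlite
Suggests: testthat (>= 3.0.0), metafor
Config/testthat/edition: 3
RoxygenNote: 7.3.3
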