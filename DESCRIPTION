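Package: galfield
Title: Living Vector Fields for Single-Cell GAL Network Induction Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Analysis pipeline for single-cell time-lapse fluorescence
    trajectories of the yeast galactose (GAL) network's two transducers,
    Gal3p and Gal1p. Converts per-cell pixel samples into robust
    fluorescence estimates (median background subtraction, skewness-gated
    puncta rejection by median absolute deviations, control-cell
    baselining), smooths and plateau-normalizes trajectories, reconstructs
    an empirical "living" vector field on the Gal3p/Gal1p state space with
    circular-variance summaries, computes a bootstrap cross-experiment
    consistency statistic of flow directions, and derives population-level
    summaries: induction-lag distributions with bootstrap confidence bands,
    viability and cell-movement curves, and a variance decomposition of
    plateau expression heterogeneity. Includes a stochastic simulator of
    bistable GAL-like induction with history-dependent initial conditions,
    sticky-region escape, lineage demography, and imaging artifacts, used
    to exercise and validate every stage of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tools,
    utils,
    yaml
Suggests:
    deSolve,
    lme4,
    testthat (>= 3.0.0),
    tidyr,
    withr
Config/testthat/edition: 3
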