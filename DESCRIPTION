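Package: pavlophys
Title: Analysis of Pavlovian Reward/Punishment Electrophysiology Sessions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing head-fixed Pavlovian reward/punishment
    discrimination sessions with simultaneous extracellular single-unit
    recordings: lick detection and statistical learning criteria, bootstrap
    power analysis for behavioural trial counts, optogenetic phototagging
    classification of projection neurons, peri-stimulus time histogram
    z-normalisation, a-priori valence/arousal response categorisation,
    population PCA state-space trajectories with leave-one-subject-out
    geometry statistics, Ward hierarchical clustering of phasic response
    profiles, and a between-trial tonic firing-rate drift test based on
    regression slopes. Includes an inhomogeneous-Poisson session simulator
    with ground-truth labels so the full pipeline can be exercised and
    validated without recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
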