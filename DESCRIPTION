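Package: voicemod
Title: Individual Differences in Volitional Social Voice Modulation
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying how specifically speakers can evoke
    intended social trait percepts (likeability, hostility, intelligence)
    in naive listeners. Computes per-speaker trait-change indices from
    7-point Likert ratings, representational similarity matrices (RSM) of
    trait ratings, and a Euclidean-distance social voice modulation index
    against a theoretical maximal-discrimination matrix. Relates
    performance to social-reactivity questionnaires (QCAE empathy
    subscales, Short Dark Triad Machiavellianism and psychopathy) through
    multiple regression with influence diagnostics, Huber M-estimator
    robust regression, and partial Pearson correlations with
    Benjamini-Hochberg false discovery rate control. Includes a voxelwise
    covariate general linear model for per-speaker contrast volumes with
    Monte-Carlo cluster-extent thresholding and cluster/peak reporting,
    plus a synthetic-data generator that emulates the full study design
    with planted ground-truth effects for calibration and recovery tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    MASS,
    optparse,
    withr
Config/testthat/edition: 3
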