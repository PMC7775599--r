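Package: larvaphenome
Title: Multi-Parameter Behavioral Phenotyping of Larval Zebrafish from Plate Tracking
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Scores photomotor locomotion, behavioral sleep and thigmotaxis of
    larval zebrafish from 2D well-centered trajectories sampled at 5 Hz by a
    multi-well plate tracking system. Movement bouts are segmented with a
    2/1 mm/s hysteresis rule, sleep is scored from 1-s movement/non-movement
    bins with the >= 6 s quiescence criterion, and wall preference is scored
    as the outer-annulus fraction of swum distance. Includes the
    normality-gated group-comparison statistics used in this assay family
    (t-test or Mann-Whitney U; one-way ANOVA/Bonferroni or
    Kruskal-Wallis/Dunn; two-way ANOVA with Tukey post hoc), a seeded
    synthetic trajectory generator implementing an alternating-renewal
    behavior model with wall-biased spatial motion and tracking dropout, and
    an end-to-end pipeline with reproducible run manifests.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    yaml,
    jsonlite,
    car,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
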