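Package: vestgait
Title: Spatiotemporal Gait Analysis for Vestibulopathy Cohort Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for clinical gait analysis of overground
    walking in vestibulopathy cohorts (bilateral and chronic unilateral
    vestibulopathy versus healthy subjects). Provides a parametric walker
    simulator with exact ground-truth gait events, marker-trajectory input
    and output with gap filling by marker inter-correlation reconstruction,
    automatic foot-strike and foot-off detection with per-trial method
    self-selection, per-cycle spatiotemporal parameters, dimensionless
    (leg-length and gravity) normalization, clinical gait scores (FGA, TUG,
    tandem walk, DHI), repeated-measures mixed-model group comparison with
    false-discovery-rate control, and SPSS-style two-step cluster analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    lme4,
    lmerTest,
    emmeans
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
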