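Package: gwgchart
Title: Gestational Weight Gain Reference Charts by Box-Cox t Distributional Regression
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Construction of gestational weight gain reference charts for
    pre-pregnancy body mass index groups. Weight gain is modelled
    cross-sectionally over gestational age with the Box-Cox t (BCT)
    distribution: four smooth parameter curves (median, variation, skewness,
    kurtosis) are estimated by penalized maximum likelihood with
    Rigby-Stasinopoulos backfitting, after a Gaussian nudge of the degenerate
    week-0 gain and a +20 kg positivity offset. Includes week-indexed
    parameter-grid export, centile curves, an exact-age z-score/percentile
    calculator, Institute of Medicine adequacy classification, model
    diagnostics (worm plots, Q statistics, centile coverage, BIC comparison
    against a linear baseline), and a synthetic longitudinal cohort generator
    anchored at published median gains for testing every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    splines,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
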