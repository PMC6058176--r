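Package: radimpact
Title: Modelling Child-Mortality Impact of Mass Radio Campaigns from
    Facility Utilisation Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating the child-mortality impact of mass media
    health campaigns from routine health-facility utilisation data. Provides
    a synthetic-data generator for cluster-randomised facility consultation
    counts, proportional compression of multi-diagnosis counts, interrupted
    time-series estimation of period-specific utilisation effects by
    mixed-effects Poisson regression with cluster-stratified BCa bootstrap
    confidence intervals, a simplified Lives Saved Tool (LiST) style
    deaths-averted engine mapping utilisation effects to treatment-coverage
    changes, and scenario algebra for penetration adjustment, discounting,
    sensitivity bounds and multi-country scale-up projections.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    lme4,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
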