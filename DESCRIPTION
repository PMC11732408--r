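Package: senodemog
Title: Demographic Analysis of Reproductive Ageing in Wild Primate Populations
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for quantifying female reproductive ageing from
    longitudinal individual-based demographic records of wild primates.
    Implements rule-based extraction of interbirth intervals and infant
    survival histories with right censoring and delayed entry, yearly
    life tables under staggered study entry, post-reproductive
    representation (PrR) with a simulation-based null test in which
    fertility and survival decline in parallel, M-spline baseline-hazard
    survival models with quadratic and time-varying maternal-age effects
    fitted by penalized maximum likelihood, prior-penalized logistic
    models of cause-specific infant mortality, and an individual-based
    life-history simulator with known ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    splines,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
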