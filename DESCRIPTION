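Package: platformtrial
Title: Bayesian Outcome-Adaptive Biomarker Platform Trial Design Engine
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Design engine and Monte Carlo simulator for a biomarker-driven,
    outcome-adaptive platform trial in metastatic castration-resistant
    prostate cancer. Implements the conjugate Gamma-Weibull survival model
    with closed-form probability of superiority, control-protected
    response-adaptive randomization stratified by biomarker subgroup
    combination, graduation/futility/cap decision rules with a
    subgroup-consistency requirement, a nested seamless confirmatory stage,
    and a replicate runner that estimates operating characteristics
    (type-I error, power, expected sample size and duration).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    survival,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
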