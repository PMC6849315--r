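Package: regval
Title: Validation of Administrative Register Procedure Codes Against Chart Review
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for diagnostic-accuracy validation of surgical procedure codes
    recorded in an administrative health register against gold-standard patient-chart
    review. Pairs register code events with chart code events per patient within a
    configurable admission-to-surgery window, classifies concordance and coding-error
    types (transposition and substitution transfer errors, omissions, spurious codes),
    cross-tabulates validation counts, and estimates positive predictive values,
    sensitivity, specificity and conditioned negative predictive values with two-stage
    hospital-clustered bootstrap percentile confidence intervals. Includes a synthetic
    register/chart data generator with controlled error injection for estimator-recovery
    and coverage studies, and report renderers for validation-study tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
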