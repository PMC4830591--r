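Package: fpicce
Title: Cost-Effectiveness of Price Subsidies on Iron-Fortified Infant Cereals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Health-economic pipeline estimating the cost-effectiveness of
    price subsidies on iron-fortified packaged infant cereals (F-PICs) in
    reducing iron-deficiency anemia (IDA) in 6-23-month-old children in large
    Indian cities.  Combines an SES-stratified burden-of-disease model
    (disability-adjusted life-years and production losses, with Gaussian
    hemoglobin-distribution calibration), first-difference panel estimation of
    price sensitivity of F-PIC demand from a two-state household survey, an
    intervention model translating demand responses into hemoglobin shifts and
    averted burden, and net-social-cost-per-DALY accounting with WHO
    cost-effectiveness classification.  Includes a synthetic market-survey
    generator with known ground truth for validating the demand estimator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
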