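Package: carbsafe
Type: Package
Title: Personalized Safe Limits for Carbohydrate Counting Errors in Type 1
    Diabetes
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computes patient-specific maximum admissible carbohydrate
    counting errors from insulin therapy parameters (insulin-to-carbohydrate
    ratio and insulin sensitivity factor) and validates them in silico. Ships
    a 33-subject virtual type 1 diabetes roster, a calibrated minimal
    glucose-insulin metabolic model with subcutaneous insulin and meal
    absorption kinetics, a 90-day open-loop basal-bolus trial engine that
    injects graded carbohydrate counting errors into every meal bolus,
    continuous-glucose-monitor style time-in-range outcome metrics, and
    paired nonparametric bootstrap inference against the error-free control
    arm.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    graphics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
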