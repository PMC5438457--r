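Package: mpssim
Title: Mobile Phone Survey Sampling Simulation with Automated Active
    Strata Monitoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates random-digit-dialing (RDD) mobile phone surveys
    against synthetic stratified populations with unequal phone ownership.
    Builds RDD sampling frames from mobile network operator prefixes,
    estimates the nonworking-number fraction and inflates sample sizes
    accordingly, runs accelerated sequential replacement of invalid
    numbers, and implements automated active strata monitoring (AASM):
    real-time quota sampling that screens each respondent and closes
    demographic strata once their targets are met. Provides the full
    post-survey weighting stack (poststratification, inverse-response-rate
    nonresponse factors, multiple-phone 1/T adjustments, weight trimming)
    with Kish design-effect diagnostics (deff = 1 + CV^2 of the weights)
    and effective sample sizes, plus closed-form selection probabilities
    for multi-phone owners. A scenario runner compares AASM against
    unrestricted RDD head-to-head on shared synthetic populations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
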