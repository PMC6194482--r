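Package: catsimr
Title: Monte Carlo Simulation of Computerized Adaptive Testing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A Monte Carlo simulation engine for computerized adaptive
    testing (CAT) under 2PL/3PL item response theory. Generates item pools
    and simulees, administers adaptive tests item by item under configurable
    scoring rules (maximum likelihood with Newton-Raphson iteration,
    maximum likelihood with fences, MAP, EAP), item selection criteria
    (maximized Fisher information, b-matching), exposure control
    (randomesque, Sympson-Hetter with iterative calibration) and
    termination rules (fixed length, standard-error threshold, score
    consistency), then evaluates measurement precision (bias, MAE, RMSE and
    their conditional variants, CSEM) and test security (item exposure
    rates, test overlap, pool utilisation).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
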