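Package: pregsim
Title: Simulating Pregnancy-Test Outcomes in Clinical Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A cohort simulator and deterministic expected-value calculator
    for pregnancy-test screening in clinical trials. Estimates rates of
    true and false negative, true and false positive ("classic" pituitary
    and "biological" chemical-pregnancy), and indeterminate pregnancy-test
    results, together with unintended embryo/fetal exposures, as a
    function of the cohort age distribution, contraception scenario, hCG
    assay characteristics (urine or serum, qualitative or quantitative,
    positive cutoff and indeterminate band), and test timing relative to
    the menstrual cycle. Ships a documented default epidemiologic and
    hCG-kinetic parameter table, a Monte Carlo engine with paired
    common-random-numbers assay comparison, a closed-form expectation
    engine for random test timing, a YAML run configuration, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
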