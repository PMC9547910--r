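Package: chronicity
Title: Claims-Based Back-Pain Chronicity Classification and Its Validation
    Against the Graded Chronic Pain Scale
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for rule-based phenotyping of chronic low back pain from
    administrative health-insurance claims (ICD-10 diagnoses, ATC-coded
    prescriptions, sick-leave episodes) and for validating the resulting
    three-level chronicity class against the self-reported Graded Chronic
    Pain Scale (GCPS). Includes GCPS scoring after von Korff, the
    12-month-lookback chronicity classifier, cohort-selection cascades,
    criterion-validity metrics (sensitivity, specificity, Matthews
    correlation coefficient, Cohen's weighted kappa, Spearman's rho with
    confidence intervals and verbal interpretation bands), health-care cost
    aggregation with consumer-price-index adjustment, Tukey-fence high-cost
    flagging and truncated means, and a seeded synthetic claims +
    questionnaire generator so the full pipeline runs without access to
    restricted insurer data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    e1071,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
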