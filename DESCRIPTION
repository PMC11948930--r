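Package: ehrconcord
Title: Concordance Between Self-Reported Survey Conditions and Electronic Health Records
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing self-reported medical conditions from
    longitudinal cohort surveys with diagnoses ascertained from coded
    electronic health records. Implements rule-based case ascertainment
    from diagnosis codes (sensitive and specific claims criteria, temporal
    restriction, multi-source merging), carry-forward survey case
    classification, Cicchetti-Feinstein positive/negative agreement and
    Youden's J, Bland-Altman agreement for height and weight, harmonization
    of smoking and alcohol-use measures, health-care utilization
    classification, and a synthetic linked-cohort generator with a
    closed-form agreement oracle for validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    tibble,
    dplyr,
    readr,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
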