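Package: rechallenge
Title: Decision Support for Chemotherapy Rechallenge After Serious
    Adverse Drug Reactions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and evaluating a clinical decision-support
    model that scores the probability of negative rechallenge (no recurrence
    of a serious adverse drug reaction on re-administration of a
    chemotherapeutic agent).  Implements clinical attribute derivation for
    patient cohorts, a mixed-type (Gaussian/categorical) naive Bayes
    classifier, ROC/AUC evaluation with clinician-chosen decision
    thresholds, a genetic-algorithm wrapper that selects predictive
    attribute subsets by AUC fitness, and a synthetic-cohort generator
    with published class-conditional statistics so the full pipeline can
    be exercised without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    e1071,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
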