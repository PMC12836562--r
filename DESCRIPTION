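Package: rarehnc
Title: Multimodal Identification of Rare Head and Neck Cancer Patients from
    Hospital EHR Extracts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A rule-based phenotyping toolkit that identifies rare head and
    neck cancer (HNC) patients from tabular electronic-health-record extracts
    by combining three evidence sources: ICD-10 hospital claims, ADICAP
    pathology codes embedded in French pathology reports, and lexicon/regex
    mining of the report free text with negation, hypothesis and
    medical-history qualification.  Builds the HNC cohort, the rare-topography
    and rare-histology subcohorts, their union, and a consolidated cohort
    requiring concordance of at least two sources; evaluates every cohort
    against gold annotations with sensitivity, specificity, PPV and NPV; and
    ships a seeded synthetic-EHR generator with per-source error injection so
    the full pipeline is testable without access to protected clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
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
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
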