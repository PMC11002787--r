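Package: respcohort
Title: Harmonised Phenotyping of Asthma, COPD and ILD Cohorts from
    Multi-Dialect Primary-Care Records
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A codelist-driven toolkit for building harmonised asthma,
    chronic obstructive pulmonary disease (COPD) and interstitial lung
    disease (ILD) cohorts from primary-care electronic health records
    that arrive in three differently coded source dialects (CPRD-like,
    SAIL-like and DataLoch-like). Provides codelist and terminology
    mapping utilities, dialect-aware imputation of birth and death
    dates, deprivation and ethnicity harmonisation, longitudinal
    cleaning of smoking, body mass index and spirometry records
    including FEV1 percent-predicted derivation and GOLD staging,
    asthma/COPD medication classification with same-day
    combination-therapy detection, and cohort description at an index
    date. A synthetic multi-dialect record generator with a latent
    truth manifest supports end-to-end validation of every stage
    without access to licensed data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    lubridate,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    stats
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml,
    knitr,
    rmarkdown
Config/testthat/edition: 3
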