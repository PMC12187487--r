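Package: dietvalidr
Title: Biomarker-Based Validity and Reproducibility Analysis of Weighed Food Records
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for validating self-reported dietary intake against recovery
    biomarkers and for quantifying the reproducibility of repeated food records.
    Implements urinary biomarker recovery equations (urea-derived nitrogen to
    protein, 24-hour urinary potassium, creatinine completeness correction),
    the energy-metabolism chain (Weir-equation indirect calorimetry, IPAQ-based
    physical activity level, total energy expenditure, Goldberg misreporting
    cut-offs), and the agreement-statistics toolkit used in dietary validation
    studies (banded Spearman correlation, regression R-squared with covariate
    adjustment, Bland-Altman limits of agreement, exact Wilcoxon signed-rank,
    paired t, intraclass correlation, Shapiro-Wilk normality gating). A
    synthetic-cohort generator emulates a two-round 7-day weighed food record
    study with configurable true-intake distributions, within-person variation,
    reporting bias and assay noise, so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
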