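Package: drgcost
Title: DRG Cost Grouping and Payment Standards for Inpatient Discharge Abstracts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Analysis pipeline for case-mix (DRG) cost grouping of hospital
    discharge-abstract records. Cleans admission records, assigns
    comorbidity/complication severity from MCC and CC code tables, screens cost
    drivers with rank-based tests, fits a log-link gamma regression for cost
    ratios and marginal means, groups admissions with an exhaustive-CHAID
    regression tree (with a CART baseline), validates groups by coefficient of
    variation and the Kruskal-Wallis test, and derives per-group payment
    standards with an interquartile-range outlier fence. A seeded synthetic
    cohort generator reproduces the statistical structure of a cerebral
    ischemia inpatient cohort so the whole pipeline runs without access to
    protected hospital data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    rpart,
    emmeans,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
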