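Package: bcrisk
Title: Breast Cancer Absolute Risk Estimation Combining Epidemiologic and
    Genetic Factors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Assembles relative-risk models for breast cancer in
    sub-Saharan African women from questionnaire-based epidemiologic risk
    factors, a polygenic risk score, and pathogenic-variant carrier status
    in high- or moderate-penetrance genes; attenuates the family-history
    coefficient for heritability already captured by the modeled variants;
    calibrates age-specific baseline hazards to population incidence; and
    projects lifetime absolute risk to age 80 under competing mortality.
    Includes discrimination (unadjusted and age-adjusted AUROC),
    threshold-based risk stratification, reclassification tables with the
    categorical net reclassification index, and a synthetic case-control
    cohort generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
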