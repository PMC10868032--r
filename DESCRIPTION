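Package: bivclean
Title: Detection of Biologically Implausible Values in Longitudinal Child
    Growth Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Staged cleaning of longitudinal length/height and weight records
    for children aged 0-59 months. Flags population outliers against a
    pluggable LMS growth reference (WHO-style z-score cutoffs), fits
    sex-specific random-intercept mixed models with restricted cubic splines
    in age, flags longitudinal outliers from scaled model residuals at
    configurable cutoffs, applies a decreasing-heights rule for implausible
    drops between visits, and reports stage-by-stage impact on stunting and
    underweight prevalence. Includes a synthetic-data generator with a
    labelled error injector for benchmarking flag sensitivity and
    specificity.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    knitr,
    lme4,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
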