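Package: dietheart
Title: Resampling Re-Analysis of Dietary Fat, Cholesterol, Blood Pressure
    and Cardiovascular Mortality
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Nonparametric resampling analyses of the diet-heart hypothesis
    on trial-style and observational-style cohorts: a permutation test for
    the between-arm difference in percent serum total cholesterol change, a
    bootstrap rank (Nelson-Aalen) test comparing cause-specific CVD-death
    hazards between cholesterol-increase and cholesterol-decrease subgroups
    under right censoring, and a binned A/B comparison of CVD-case mean
    cholesterol against percentile-bootstrap confidence intervals of the
    population mean across diastolic blood pressure strata. Includes
    synthetic cohort generators calibrated to the Minnesota Coronary
    Experiment and Framingham Heart Study summary structure, CSV cohort IO,
    seeded reproducible pipelines, and machine-readable reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    knitr,
    optparse,
    rmarkdown,
    survival,
    testthat (>= 3.0.0),
    withr,
    yaml
VignetteBuilder: knitr
Config/testthat/edition: 3
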