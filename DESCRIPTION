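Package: splitmr
Title: Split-Sample Mendelian Randomization of Hormonal Exposures on
    Socioeconomic Outcomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for split-sample Mendelian randomization (MR) analyses of
    circulating hormone exposures, built around a synthetic biobank-style
    cohort simulator with configurable confounding, pleiotropy and reverse
    causation. Includes derivation of free and bioavailable testosterone from
    total testosterone, SHBG and albumin (Vermeulen equilibrium equations with
    an assay detection floor), per-SNP least-squares GWAS, greedy LD clumping,
    polygenic score construction, one-sample MR by two-stage least squares
    with heteroskedasticity-robust standard errors and weak-instrument F
    statistics, multivariable-adjusted comparators with Hausman and Fisher
    estimate-difference tests, fixed-effect meta-analysis across splits, and a
    two-sample summary-statistic sensitivity suite (IVW, MR-Egger, weighted
    median, weighted mode, Cochran's Q). A pipeline driver codes income,
    employment, deprivation and education outcomes and orchestrates the full
    stratified split-sample analysis, including negative controls and
    reverse-direction (education to hormone) MR.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    sandwich,
    metafor,
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
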