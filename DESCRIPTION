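Package: powergap
Title: Audit of Effect-Size Assumptions and Ceiling Effects in Two-Arm Trials
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for meta-research audits of two-arm randomized controlled
    trials with a continuous primary outcome. Recovers pooled standard
    deviations from reported standard errors or confidence intervals,
    normalizes outcome summaries onto bounded patient-reported outcome
    (PROM) scales as percent-of-best-score, flags possible ceiling effects
    (weighted mean plus k pooled SDs crossing the best score), compares
    observed standardized effect sizes against the effect sizes assumed in
    a-priori power calculations, and renders the frequency and
    cross-tabulation report tables such audits publish. Includes a seeded
    synthetic trial-registry generator with boundary-censored (clipped
    normal) outcomes and inflated power-calculation estimates so the whole
    pipeline is testable without access to any extracted dataset.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    jsonlite,
    readr,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
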