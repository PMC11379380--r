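Package: naphrisk
Title: Probabilistic Naphthalene Health-Risk Assessment from Urinary and
    Hair 2-Hydroxynaphthalene Biomonitoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for biomarker-based probabilistic health-risk assessment
    of naphthalene exposure. Converts urinary and hair concentrations of the
    metabolite 2-hydroxynaphthalene (2-OHNAP) into estimated daily intake
    (EDI) of the parent compound by reverse dosimetry, propagates input
    variability through hazard-quotient (HQ) and carcinogenic-risk (CR)
    formulas by Monte-Carlo simulation, and summarises the simulated risk
    distributions (P5, mean, P95, exceedance fractions). Includes handling of
    left-censored (non-detect) concentrations by LOD/2 substitution,
    creatinine normalisation of urinary measurements, a calibrated synthetic
    cohort generator for reproducible end-to-end runs, and the descriptive
    and nonparametric statistics used in human biomonitoring studies
    (Mann-Whitney, Kruskal-Wallis, Spearman, Lilliefors-corrected
    Kolmogorov-Smirnov).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    nortest,
    purrr,
    readr,
    rlang (>= 1.0.0),
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
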