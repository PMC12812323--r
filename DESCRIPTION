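Package: hfmos
Title: Medication Optimization Scoring and Longitudinal Outcome Models for
    Heart Failure Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying guideline-directed medical therapy (GDMT)
    in heart failure with reduced ejection fraction and for modelling its
    association with clinical outcomes. Implements the Medication
    Optimization Score (MOS) with eligibility gating, intolerance-aware
    denominators and per-class recommendations, together with the Heart
    Failure Collaboratory (HFC), modified HFC and Kansas City Medical
    Optimization comparator scores, the Charlson Comorbidity Index and an
    ordinal heart-failure severity index. Provides a synthetic electronic
    health-record cohort generator with known causal truth (upward dose
    titration, treatment-confounder feedback, distance-dependent censoring),
    a six-month-interval exposure panel builder in counting-process form,
    Kaplan-Meier and Cox analyses, a marginal structural Cox model with
    stabilized inverse-probability-of-treatment and censoring weights for a
    continuous exposure, and a random-slope linear mixed model for score
    trajectories.
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
    lme4,
    purrr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
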