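Package: pddm
Title: Iterated Prisoner's Dilemma Task Engine and Drift-Diffusion Analysis for
    Stimulation Crossover Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates and analyses a sham-controlled crossover study of
    transcutaneous vagus nerve stimulation (tVNS) effects on cooperation in an
    iterated prisoner's dilemma. Provides the computerised task engine (eight
    opponents with cooperative, deceitful, tit-for-tat and random policies,
    payoff accounting, closed-form point expectations), a synthetic-cohort
    generator whose choices and reaction times arise from a drift-diffusion
    process with stimulation-dependent starting bias and drift, a from-scratch
    Wiener first-passage-time likelihood with nested-model comparison by
    chi-square difference tests, and the group-level statistical chain
    (trial cleaning, repeated-measures ANOVA with paired effect sizes,
    collinearity-screened mixed-effects logistic regression, post-hoc
    correlations, paired power analysis).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    lme4,
    pracma,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
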