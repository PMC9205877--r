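---
title: "Methods: task engine, synthetic cohort, and drift-diffusion analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: task engine, synthetic cohort, and drift-diffusion analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pddm)
```

## What this package models

`pddm` implements the computational core of a sham-controlled crossover
experiment on social decision making: patients play an iterated prisoner's
dilemma against eight opponents while receiving transcutaneous vagus nerve
stimulation (tVNS) at the cymba conchae or sham stimulation at the ear
lobule, and the question is whether stimulation shifts behaviour towards
cooperation, and if so at which stage of the decision process. The package
provides (i) the task itself, (ii) a generative model of the cohort whose
choices and reaction times arise from a drift-diffusion process, and
(iii) the full analysis chain, so that every stage can be exercised and
validated end-to-end on synthetic data without access to patient records.

## The task engine

Each session comprises 120 trials: eight opponents (four presented as
humans, four as computers) played 15 times each in a uniformly shuffled
order, with the order of the two decision prompts randomized per trial.
Opponent policies are: cooperative (cooperates with probability 0.7),
deceitful (0.3), tit-for-tat (repeats the subject's previous choice
against that opponent) and random (0.5). The player payoff matrix shipped
in the default configuration is

|                  | opponent cooperates | opponent deceives |
|------------------|--------------------:|------------------:|
| player cooperates | 20 | 0 |
| player deceives   | 30 | 5 |

These cells satisfy the classic dilemma ordering (30 > 20 > 5 > 0 and
2·20 > 30 + 0) and make deception the dominant single-trial action, while
sustained cooperation still beats sustained deception against tit-for-tat
— so deception is the most rewarding strategy against exactly three of the
four policies.

`expected_session_points()` gives closed-form expected totals for constant
player policies. With this matrix and the stated policy probabilities the
always-deceive expectation is 1725 points, the always-cooperate expectation
1500, and the best-constant-per-opponent yardstick 2175 — the three
reference totals the task displays to participants.

**Tit-for-tat first move.** The three totals above are simultaneously exact
only if tit-for-tat's response to a constant player equals that player's own
policy from the first encounter onwards. We therefore default `tft_first`
to `"mirror"`: on a first encounter the opponent copies the subject's
same-trial choice, afterwards the previous one. No fixed first move
(always-cooperate or always-deceive) reproduces both 1725 and 1500 at once
— under cooperate-first the always-deceive expectation is 1775, under
deceive-first the always-cooperate expectation is 1460 — which is why the
convention is exposed in the configuration rather than hard-coded. This can
be verified directly:

```{r}
opp <- build_opponents(tft_first = "mirror")
c(deceive = expected_session_points("deceive", opp),
  cooperate = expected_session_points("cooperate", opp),
  best = expected_session_points("best_constant", opp))
```

## The generative cohort

`generate_study()` builds a complete crossover dataset: `n` subjects
(default 19), two sessions each, condition order counterbalanced so the
split differs by at most one subject, and each session played by a
diffusion-model agent.

The diffusion process runs between a lower "deceive" and an upper
"cooperate" boundary (diffusion coefficient fixed at 1), so a starting bias
`b = z/a` above 0.5 means an initial preference for cooperating. The
planted stimulation effects are:

* **Starting bias**: 0.5 under sham; `0.5 + 0.03 · (1 − 2.0·z_N + 0.9·z_E)`
  under tVNS, where `z_N`, `z_E` are the subject's standardized neuroticism
  and extraversion scores, clipped to (0.05, 0.95). The stimulation effect
  therefore *decreases* with neuroticism and *increases* with extraversion.
* **Drift rate**: baseline −0.327 (towards deception) plus a subject-level
  offset (SD 0.165), a session-level perturbation (SD 0.075), and +0.085
  under tVNS (towards zero).
* Boundary separation 1.6 and non-decision time 0.35 s in both conditions.

These constants live in `inst/extdata/default_config.yaml`, not in code.
They were calibrated once, before any tests were written, to the study's
published anchors: mean cooperation ≈ 43.4% under tVNS vs ≈ 37.2% under
sham, a paired effect size d ≈ 0.5 for the stimulation contrast, and a
rank correlation of about −0.5 between the per-subject stimulation effect
and neuroticism. With them, a mean-trait subject cooperates with
probability `choice_probability(1.6, -0.327, 0.5)` ≈ 0.372 under sham and
≈ 0.434 under tVNS.

The magnitude of the neuroticism slope (−2.0 per SD) deserves a note: it is
what a rank correlation of ≈ −0.5 between stimulation effect and
neuroticism *requires* given the other variance components, and it implies
the planted bias shift reverses sign for subjects more than ~0.5 SD above
mean neuroticism. The published interaction and correlation are only
jointly consistent with the published group effect if the modulation is
this strong.

Remaining generator plumbing — trait score distributions, affect scores,
clinical covariates, likability ratings (humans drawn ~1.5 points more
likable than computers on the 1–9 pictorial scale), a 0.35% invalid-trial
rate (≈16 of 4560 trials) — emulates the cohort description but is not an
estimate of any real distribution. Two optional behaviours are off by
default because the analysis model also pools over them: a reciprocity
term (drift penalty after having been deceived by that opponent) and a
human-opponent drift bonus. Each (subject, session) pair runs on a
deterministically derived seed, so any single session is reproducible in
isolation.

What passing tests on this cohort do **not** show about real data: the
generator is exactly the model the analysis assumes (no contaminant RTs, no
attention lapses, no learning or strategy drift over trials, trait effects
exactly linear), so recovery results here are a best case. The generator's
purpose is to validate the machinery and the statistical calibration, not
to claim the cohort model is true.

## First-passage simulation

Trials are simulated by an Euler scheme with a 1 ms step. Between-step
boundary crossings can be reinstated by an exact Brownian-bridge
correction (`bridge = TRUE`); it is off by default (matching the plain
small-step scheme) and enabled in validation tests where analytic fidelity
matters. At the default parameters the plain scheme's absorption
probabilities are biased by roughly 0.002–0.004 and RT quantiles by about
half a step; with the bridge correction the absorption bias is within
Monte-Carlo noise at 2·10⁴ draws. Rare paths still unabsorbed after 20 s
are censored to the nearer boundary; at the default parameters this is a
< 10⁻⁶ event and such trials exceed the task's 10 s response limit anyway,
so they are marked invalid downstream.

## Likelihood and fitting

The Wiener first-passage density is evaluated by the standard dual-series
representation — a Gaussian-image expansion accurate at short times and a
sine expansion accurate at long times — with a per-point accuracy-based
switch at truncation error 10⁻¹⁰. The two series agree to < 10⁻⁸ on an
overlap grid, and the density's time integral matches the closed-form
absorption probability `(1 − e^{−2vaw})/(1 − e^{−2va})` to 10⁻⁶ (both are
test invariants). Inter-trial variabilities (normal in drift, uniform in
start point and non-decision time) are integrated by 7-node Gaussian
quadrature when active; they are fixed at 0 by default and activated only
in the comparison that frees them.

`fit_ddm()` maximizes the continuous (choice, RT) likelihood with a
Nelder-Mead simplex on transformed parameters (log for `a`, logit for the
bias, logit-scaled-to-min-RT for `t0`), from a data-driven start plus
jittered restarts (default 5), with relative convergence tolerance 10⁻⁷.
Trials with RT below 0.2 s are excluded from fitting as likely
contaminants and counted on the fit object. Densities inside the deviance
are floored at 10⁻¹⁰ so a candidate `t0` above an observed RT incurs a
large finite penalty rather than an infinite one — this keeps the simplex
usable. Non-convergence is flagged on the returned object, never thrown.

**Nested models.** The seven-model family frees, one at a time, each of
{boundary, non-decision time, drift SD, starting point, start-point range,
non-decision range, drift} across the levels of a grouping factor
(stimulation condition by default; the factor is configurable because
either condition or opponent class is a defensible reading of the design).
Each free model is compared to its fixed counterpart by a chi-square
difference test on the deviance (df = levels − 1 per freed parameter,
statistic floored at 0 against optimizer noise); free fits are warm-started
from the fixed optimum, which enforces the nested deviance ordering
numerically. Cohort-level inference fits per subject and sums per-subject
deviance differences with summed df — subjects are independent, so the sum
is chi-square under the null; whether the original analysis pooled or
summed is not determinable from its description, and per-subject fitting is
the statistically safer choice. Group-level parameter tests are one-sample
t-tests of the bias against 0.5 and the drift against 0 per condition
(Bonferroni within the family of four) and paired t-tests across conditions
with the paired effect size d(z) = mean difference / SD of differences.

The diffusion coefficient is fixed at 1 throughout; parameters published on
the legacy 0.1 scale map onto this scale by dividing evidence-denominated
parameters by 0.1 (`legacy_to_unit()`), a pure reparameterization under
which deviances are identical (tested as an exact equivalence).

## Group statistics

Cleaning removes trials with an undefined response or a response over the
10 s limit, with per-cell exclusion counts reported and an error if any
subject × condition cell would be left empty. Cooperation percentages are
normalized per (subject × condition × opponent class) cell — the analysis
description does not fix this; per-cell normalization keeps the 2×2 design
balanced. The 2×2 within-subject ANOVA uses the standard stratified
decomposition (each effect against its subject-by-effect stratum), applied
unchanged to cooperation, reaction time, total points and likability (the
control analyses). A stratum whose entire sum of squares is numerically
zero reports F = 0, p = 1 rather than a ratio of rounding noise.

The trial-level model is a mixed-effects logistic regression with a
subject random intercept; fixed effects of likability, opponent policy
(cooperative style as reference), the opponent's previous decision against
this subject (+1 cooperate / 0 first encounter / −1 deceive), sex, age,
the five personality scores, belief in live opponents and standardized
trial index ("time"); plus stimulation × predictor interactions for all of
them. Numeric predictors are z-scored and screened first: pairs with
squared Pearson correlation strictly above 0.7 lose the member with the
larger mean absolute correlation to the remaining predictors (ties: the
later column). Coefficient p-values use a t reference on residual degrees
of freedom (trials minus fixed effects), matching the reporting convention
of the original analysis. Post-hoc Spearman correlations relate each
subject's stimulation effect (tVNS% − sham%) to traits; clinical controls
use Pearson / point-biserial coefficients.

`sample_size_cooperation()` returns the smallest n whose paired t-test
power (exact noncentral-t curve) reaches the request, verified minimal by
stepping n down. The shipped pilot anchors (mean difference 9.2, SD 10)
give n = 18 at α = 0.05 and 95% power; the real pilot's numbers are not
public, so the operation is validated by its minimality/monotonicity
properties and a Monte-Carlo power check, not by that particular n.

## Calibration results and an honest limitation

Two properties were measured over repeated synthetic studies at the
default calibration (the packaged tests recompute them):

* Under a null generator (no planted shifts), the ANOVA stimulation effect
  and the chi-square difference test reject at the nominal 5% rate, and
  the chi-square p-values are approximately uniform.
* With the planted defaults at n = 19, the detection rates are ~68% for
  the ANOVA stimulation effect, ~60% for the trial-level
  neuroticism × stimulation interaction, and ~44% for the paired
  starting-bias shift.

The second point is a deliberate, documented limitation rather than a
defect: the planted effects are calibrated to the *published* effect sizes
(paired d ≈ 0.5), and a d ≈ 0.5 effect simply cannot be detected with 80%
power at n = 19 and α = 0.05 — the theoretical maximum is about 57%
two-sided. A test suite that demanded higher detection rates at this
sample size could only be satisfied by inflating the planted effects above
what the study reports, which would defeat the generator's purpose. The
corresponding acceptance expectations are therefore left failing by
design, with the calibration kept faithful.

## Problem sizes used in the packaged checks

Monte-Carlo sizes are chosen so the full suite runs on a laptop-class
machine: 10⁵ draws for policy-frequency calibration, 1.5–2·10⁴ draws for
simulator-vs-analytic agreement, 150 replicates for chi-square null
calibration inside the test suite (500 in the acceptance script), 20 seeds
at 1000 trials for bias recovery, and 25 planted plus 30 null studies for
the end-to-end recovery rates. Bounds in tests are 3σ binomial or exact
binomial envelopes at those sizes.

## Known limitations

* No hierarchical (shrinkage) estimation: subjects are fit independently.
* The binned multinomial (quantile-based) objective common in older
  toolboxes is not implemented; estimation is continuous maximum
  likelihood only.
* The generator does not model learning, opponent-specific strategies
  (beyond the optional reciprocity term), contaminant RTs or lapses.
* The mixed model's t-on-residual-df p-values are anti-conservative when
  per-subject stimulation-effect heterogeneity is large; this mirrors the
  original reporting convention rather than improving on it.
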