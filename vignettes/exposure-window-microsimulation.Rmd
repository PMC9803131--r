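---
title: "Estimating exposure over a time window by cohort microsimulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating exposure over a time window by cohort microsimulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(expowin)
```

## The problem

Burden-of-disease calculations need the number of people exposed to a risk
factor *over a multi-year time window* (year~t~ to year~t+n~), not just in a
single year: a person who worked ≥55 hours/week in any year of the window
counts as exposed for outcomes with a long lag. Surveys deliver point
prevalence per year; the link between point and period prevalence is the
occupational turnover ratio OT = period / point, historically set to a
constant (4 or 6). `expowin` replaces the constant with an explicit
microsimulation driven by three fitted models.

## The three models

**Model 1 — prevalence at the window's first year.** For each exposure
category $i$ the cell-level proportion follows a linear trend in calendar
year,

$$\mathrm{proportion}_i = A_i(\mathrm{sex},\mathrm{age},\mathrm{country})
  + B_i(\mathrm{sex},\mathrm{age},\mathrm{country}) \times \mathrm{year},$$

with normal residuals on the proportion scale and age group treated as
categorical. With one country (the usual case) this is a weighted
fixed-effects regression of cell proportions on year within each
sex × age-group cell (`prevalence_trend()`, engine `"cell"`); with several
countries a multilevel version (lme4) places random intercepts and year
slopes per sex × age group nested in country (engine `"lmm"`). Because $K$
categories are fitted independently, predictions need not lie in the simplex;
`predict()` therefore clamps raw predictions to [0, 1] and renormalises, and
reports both vectors. Year is centred at the window's first year for
numerical stability, so $A_i$ is directly the prevalence at year~t~.

**Model 2 — annual transition probabilities.** Pseudo-longitudinal pairs are
built by matching consecutive survey waves on the quasi-identifiers
(household number, household sequence number, sex, year of birth); ambiguous
keys are discarded, and the matched sample is post-stratified to
cross-sectional margins by labour status, sex and 10-year age group
(`match_pseudo_panel()`, `reweight_panel()`). Per *origin* category, a
weighted multinomial logit models the destination category,

$$p_j = \frac{e^{\beta_j^\top x}}{1 + \sum_\alpha e^{\beta_\alpha^\top x}},$$

with the transition into category 0 as pivot outcome ($\beta_0 = 0$) and
$x$ = intercept, sex indicator, and fractional-polynomial (FP) terms in age.
FP powers come from \{-2, -1, -0.5, 0, 0.5, 1, 2, 3\} (0 meaning $\ln x$;
a repeated power multiplying the second term by $\ln x$), degree at most 2;
all 8 + 36 = 44 candidates are fitted exhaustively and the lowest-deviance
model is selected (`select_fp()`), with ties broken toward lower degree and
lexicographically smaller powers. Deviance is −2 × the maximised weighted
log-likelihood; weights are treated as probability weights (they scale the
likelihood, so point estimates are exact while model-based standard errors
are approximate). 95% uncertainty ranges for predicted probabilities come
from the delta method on the fit's covariance. Predicted matrices
(`predict()` on a `transfit`) are row-stochastic by construction and a
single age-continuous model serves all window years.

**Model 3 — the microsimulation.** A synthetic cohort (reference size
n = 200,000) is initialised to the population's sex × age structure by
largest-remainder rounding, with exact ages uniform within 5-year bands and
initial categories drawn from the Model 1 prevalence (Step A). Each year the
cohort ages by one; a uniform draw against the life-table death probability
q(sex, age, year) censors individuals (death is absorbing), and survivors
transition by inverse-CDF sampling of the transition row for their sex and
exact integer age (Step B). After the window, mortality-only years run up to
the estimation year year~a~ (Step C). Among those alive at year~a~, each
individual's window sequence $S_l$ is reduced to one category and the period
prevalence of category $k$ is

$$\mathrm{proportion}_k = \frac{1}{n}\sum_l \delta_{k,\max(S_l)},$$

with $\delta$ the Kronecker delta. Besides the `max` rule two alternatives
are provided: the highest category held at least two consecutive years
(`max2`) and the most-time (modal) category (`most`).

## The exact oracle

Because mortality does not depend on the exposure category, the distribution
of $\max(S_l)$ conditional on survival equals its unconditional distribution
for a fixed cohort profile. `exact_period_prevalence()` exploits this with
dynamic programming over the joint state (current category, maximum so far),
giving exact period prevalence for K ≤ 8 and windows ≤ 15 transitions; the
alternative rules are handled by full path enumeration on tiny systems
(K ≤ 3, ≤ 6 transitions). The oracle verifies the Monte Carlo engine
(`mc_period_prevalence()`) at binomial tolerance and serves as the
deterministic backend (`backend = "dp"`) for uncertainty propagation.

## Uncertainty and sensitivity

`bootstrap_period_prevalence()` re-evaluates the simulation B times
(reference B = 1000; tests use smaller B) with inputs drawn independently
from normal distributions centred at their point estimates — prevalence
vectors are clamped to [0, 1] and renormalised, transition rows renormalised,
death probabilities clamped; irreparable draws are rejected and redrawn (cap
10 B). The 2.5%, 50% and 97.5% quantiles of the replicates give (lower,
point, upper); the unperturbed point is reported alongside. Printed ranges
convert to sampling sds by sd = (upper − lower)/(2 × 1.959964)
(`sd_from_ur()`). `sensitivity_tornado()` runs the power set of the three
input-uncertainty toggles and reports median relative errors, and
`noise_scaling_experiment()` checks that Monte Carlo noise decays as
$n^{-1/2}$ — the law-of-large-numbers scaling; the fitted log–log slope is
expected in [−0.6, −0.4].

## The synthetic-data generator

`make_truth()` builds a fully known world: per-cell linear prevalence
trends (Dirichlet intercepts; zero-sum slopes of typical magnitude 0.003/yr
kept inside the simplex over the year range), an age-smooth transition truth
(per-origin multinomial logit in age/50 and (age/50)², additive sex effect,
diagonal persistence of 2.8 logit units so annual stay-put probabilities
fall in the realistic 0.45–0.9 range — and, deliberately, in the regime
where the FP machinery can recover the truth from panels of the size the
package targets), a Gompertz life table q = min(1, a e^{b·age}) with
sex-specific a and b = 0.095, and a smooth two-sex, 17-band population
pyramid. `sample_cross_sections()` and `sample_rotating_panel()` draw
survey-like data, the latter with configurable attrition and key-collision
fractions to exercise the matcher's discard rule. Ages within 5-year bands
are uniform (the open band spans 95–99). What the generator does *not*
emulate: quarterly rotation structure, questionnaire effects, correlated
household behaviour, non-Markov exposure histories, and measurement error —
so green tests show the estimators recover a world of this structure, not
that real surveys satisfy it.

## Numerical choices and conventions

* **Event order** within a simulated year: age increment, then mortality,
  then transition. The DP oracle mirrors this order exactly.
* **RNG**: one seeded stream per simulation call, with draws vectorised in
  fixed individual order — runs are bit-reproducible for a given seed. (No
  parallelism is used, so per-individual streams would add cost without
  benefit.)
* **Inverse-CDF rule**: the next category is the smallest $k$ with
  $u < \sum_{j\le k} p_j$; `step_transition()` exposes the scalar rule.
* **Pivot**: category 0 per origin; predicted probabilities are invariant to
  the pivot (tested), so the choice is inconsequential.
* **Unobserved destinations** from an origin get probability 0, with an
  optional Laplace-style floor (`floor` argument, default 0).
* **FP optimisation**: FP columns are rescaled to unit max-magnitude before
  optimisation (x³ and x⁻² differ by ~8 orders of magnitude at adult ages)
  and coefficients mapped back — a pure reparametrisation that changes no
  fitted probability or deviance; no Royston pre-scaling of age itself is
  applied since ages ≥ 15 are safely positive.
* **OT orientation**: OT = period/point, so point × OT = period — the
  direction in which a constant OT of 4 has been applied in earlier studies.
* **`max2` fallback**: individuals with no category held ≥ 2 consecutive
  years keep their sequence maximum; `most` ties resolve to the higher
  category, conservative toward exposure.
* **Degenerate inputs**: zero-weight survey cells are dropped with a
  warning; a single survey year is an error (the slope is unidentifiable);
  strata with zero survivors report missing proportions with an alive count
  of 0; missing interior life-table ages are filled by nearest-age
  carry-forward with a warning.

## Problem sizes used by the tests

The oracle-equivalence check runs 20 random 6-category systems with 10-year
windows at the reference cohort size n = 200,000; noise scaling uses
n ∈ {1000, 4000, 16000, 64000} with 30 replicates; Model 2 recovery fits a
~50,000-pair panel; bootstrap coverage uses B = 200 with the exact backend
over 10 strata. These sizes keep the full suite to a few minutes while
leaving the binomial tolerances meaningful. One caution from our own
experiments: a worst-cell (sup-norm) recovery criterion over hundreds of
predicted transition cells sits close to its sampling noise floor at 50,000
pairs — per-cell errors have sd ≈ 0.006–0.011, so the maximum across cells
concentrates near 0.02–0.035 even when the fitted family contains the truth;
median cell errors are an order of magnitude smaller.

## Limitations

Transitions are first-order Markov in the current category, sex and age;
exposure-history dependence is out of scope. The linear probability model
for prevalence can predict outside [0, 1] and relies on clamping; a logit
link is deliberately not used to keep the stated model. Bootstrap
perturbations are independent across inputs and cells except for
renormalisation. The deterministic backend reduces each stratum to a
representative age (band midpoint), an approximation the Monte Carlo
backend does not make.
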