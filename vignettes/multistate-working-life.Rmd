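---
title: "Multistate working-life tables: models, conventions and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multistate working-life tables: models, conventions and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

worklife implements the discrete-time, incidence-based multistate life-table
analysis of working life: yearly labor-market states, multinomial-logit
transition probabilities, and the partition of life expectancy (LE) at a
baseline age into state-specific expectancies. This vignette documents the
model, the conventions the package adopts where the methodology leaves
choices open, and what the synthetic validation does and does not
demonstrate.

## The state space and classification rules

Each person contributes one record per calendar year, classified into
exactly one of six states: `full_year` (employed more than 350 days),
`mid_low` (employed 30 to 350 days, a closed interval), `unemp_inactive`
(unemployed, inactive, or employed fewer than 30 days), `disability`
(disability pension), `retired` (old-age pension), and the absorbing `dead`
(died at any time in the year). Education is the highest degree obtained,
in three ISCED 2011 groups: low (0–2), mid (3–4), high (5–8).

Two conventions deserve comment:

* **Rule precedence.** The state definitions are mutually exclusive only
  once a precedence is fixed for records where a pension flag co-occurs
  with 30+ employment days. Death always dominates. The default order —
  death, old-age pension, disability pension, then the day-count rules —
  reflects that pension receipt defines the exit states in this analysis;
  `classify_states(precedence = ...)` makes the choice explicit and
  configurable, and every study manifest records it.
* **Boundaries.** "More than 350 days" is strict (351 days and up), the
  mid/low interval is closed at both ends, and "fewer than 30" is strict.
  Day counts are capped at 366; leap years do not move the thresholds.

A censored (outmigrated) person-year contributes its state for that year
but no outgoing transition: the censoring year appears as a destination,
never as an origin.

## Transition model

Transitions from origin state $o$ at age $x$ to destination $d$ at age
$x+1$ follow a multinomial logit, stratified by gender and origin state,
with the staying destination ($d = o$) as reference:

$$\log \frac{P(d \mid o, x, \text{edu})}{P(o \mid o, x, \text{edu})} =
\beta_{0} + \beta_{1} z + \beta_{2} z^2 + \beta_{3} z^3 +
\gamma_{\text{mid}} + \gamma_{\text{high}}, \qquad z = \frac{x - 70}{10}.$$

Fitting one model per gender × origin is equivalent to a single
fully-interacted multinomial regression per gender and matches how
discrete-time multistate software parameterizes transitions; education
enters as a covariate rather than a stratum, so each gender's expectancies
by education derive from one fitted model. Age is centered at 70 and scaled
by 10 purely for numerical conditioning of the cubic; the centering is
stored in the model object and predictions are invariant to it (asserted in
the test suite to 1e-8).

Estimation is by Newton–Raphson on the grouped (sufficient-statistic) form
of the weighted multinomial likelihood: the likelihood depends on the data
only through weighted destination counts per unique (age, education) cell,
so iterations cost the same at 5,000 and 500,000 observations. Step-halving
enforces a monotone penalized log-likelihood trace (kept in the
diagnostics); convergence is declared when the relative log-likelihood
change falls below `tol` (default 1e-10) or when no ascent step remains at
machine precision. Row weights are exactly equivalent to duplicating
observations, which is what makes the clustered bootstrap below exact.

**Separation.** A destination never observed from an origin is dropped with
a warning and given probability exactly zero. A destination observed only a
handful of times can drive the true maximum likelihood to infinity
(quasi-separation); the optional ridge penalty `ridge_lambda` on the
non-intercept coefficients (default 0, with 1e-6 the recommended value for
sparse origins and small samples) bounds the optimum with negligible effect
on well-identified coefficients. The fitted-versus-`nnet::multinom`
cross-check in the tests runs at ridge 0.

**Structural zeros.** A transition mask turns cells off at the linear
predictor ($-\infty$ before the softmax), not by post-hoc rescaling, so the
remaining probabilities are still a proper multinomial.

## Life-table machinery

Given age-specific matrices $P(x)$ for one profile on the grid
$x = 30, \dots, 109$, the chain's marginal distribution is propagated as
$\ell(x+1) = \ell(x) P(x)$ from an initial distribution over living states,
and the expectancy for state $s$ is
$e_s = \sum_{x=30}^{109} \ell_s(x)$, with $LE = \sum_s e_s$ by
construction (conservation is asserted to 1e-10 throughout).

Conventions, each of which the methodology leaves open:

* **Exposure.** One full year is credited to the state occupied at the
  start of each yearly interval, the plain discrete-time convention. A
  half-year death-interval adjustment (`death_year_credit = 0.5`) is
  available; on the packaged synthetic populations it lowers total LE by
  roughly half a year times the lifetime death mass, i.e. by less than
  0.5 years, and state partitions shift accordingly.
* **Terminal closure.** The grid is closed at age 110: no exposure is
  credited at or beyond 110, equivalent to forcing all living states into
  death there. Recomputing with closure at 100 or 120 is a one-argument
  change (`terminal_age`) and its effect is bounded by the survival mass
  beyond the closure age.
* **Initial distribution.** "Unconditional" expectancies start from the
  observed mix of living states at the baseline age per profile
  (`unconditional_init_distribution()`), with a configurable ±k-year
  pooling window for sparse cells (the studies in this package pool ages
  28–32, i.e. `age_window = 2`, since single-year-of-age cells are thin at
  realistic sample sizes). A fixed one-state radix gives conditional
  expectancies instead.
* **Tolerances.** Row-stochasticity is validated at 1e-9 on input and
  restored to machine accuracy by exact renormalization; occupancy vectors
  then sum to 1 within 1e-10 over an 80-year grid.

An independent Monte-Carlo oracle (`monte_carlo_expectancies()`) estimates
the same quantities by simulating individual trajectories and averaging
state-years under the same exposure convention; the matrix and trajectory
routes agree within Monte-Carlo error on arbitrary stochastic matrices, and
the closed-form single-state chain $\sum_k (1-q)^k$ is reproduced to 1e-12.

Uncertainty comes from a clustered bootstrap: persons (entire trajectories)
are resampled with replacement and the whole pipeline re-run per replicate.
A person drawn $k$ times enters as weight $k$ — identical to physical
duplication by the weight equivalence above — so replicates reuse the
grouped design matrices and are warm-started from the point estimate.
Replicate refits use a relative tolerance of 1e-8; the induced expectancy
perturbation is orders of magnitude below percentile-interval widths.

## The synthetic register generator

Real register data of this kind are not publicly deposited, so validation
rests on a generator with fully known ground truth
(`default_ground_truth()`): the same cubic-age multinomial logits, per
gender and origin, with education contrasts. The packaged coefficients are
synthetic. They were chosen once to be demographically plausible — LE at 30
near 50 years for men and 54 for women, roughly 20 years of full-year work,
mortality rising with age and steeper for the low educated, retirement
concentrating in the mid-60s, re-entry into work after jobless spells — and
to encode the qualitative gradients the working-life literature reports.
Two presets sharpen the contrasts (`finland_like`: larger education gaps,
small gender gaps; `italy_like`: large gender gaps in joblessness, earlier
retirement, more disability years). They are labelled synthetic everywhere;
none of them reproduces a real country's registers.

The generator emulates: a 2005 cross-section of adults aged 30–80 followed
through 2018, entry states drawn from the truth chain's occupancy
conditional on being alive at the entry age (so sample prevalence at any
age converges to the chain's own occupancy), yearly transitions, uniform
employment-day back-fill within each state's day interval (any distribution
consistent with the thresholds would do; uniform is the least informative),
a small annual outmigration hazard (0.005), administrative truncation at
the window's end without a censoring flag, and optional return migration
(default off). The year a person dies is emitted as a final record flagged
`died_in_year`, so the death transition is observed from its true origin
state at its true age.

What it does not emulate: survey sampling and response weights, linkage
error, institutionalized-population exclusions, duration dependence
(the generator is exactly Markovian), calendar-period effects (the truth is
a single period model, as is the estimator), and item-level measurement
error in employment days. Passing recovery tests therefore demonstrates
internal correctness of classification, estimation and life-table
computation — not robustness to non-Markov dynamics or measurement problems
in real registers.

One seeded RNG stream drives the whole generator with fully vectorized
year-stepping; identical seed and configuration give byte-identical output.
Per-person substreams were considered and rejected: base R has no cheap
substream API, and the testable contract is dataset-level reproducibility.

## Validation design and problem sizes

The test suite validates each stage against an independent route: hand
tallies for classification, brute-force pair counting for transition
observations, count-ratio oracles and `nnet::multinom` for the estimator,
closed forms and trajectory simulation for the life table, and
parameter-recovery and interval-coverage experiments for the pipeline.
The study sizes used by the packaged experiments are 50,000 persons for
recovery and null-gap checks, 20 replicates of 10,000 persons for
Wald-interval coverage, and 20 outer replicates with 200 bootstrap
replicates at 10,000 persons for bootstrap coverage; trajectory-oracle
comparisons use 200,000 simulated paths.

A known sensitivity: with entry ages capped at 80 in 2005, no transitions
are observed beyond age 93, so matrices for ages 94–109 are cubic
extrapolation. The extrapolated death logit inherits the sampling noise of
the cubic term amplified by $z^3$, and roughly half of the variance of
recovered total LE at realistic sample sizes comes from this region (the
rest is ordinary in-sample sampling error, whose profile-level standard
deviation is about 0.4 years at 50,000 persons). Populations whose oldest
entrants are older, or a lower terminal age, shrink this component; the
package deliberately leaves the estimator unregularized in that region
rather than imposing a mortality closure that the fitted model family does
not contain.

## Limitations

* The Markov assumption: next-year state depends only on current state,
  age, gender and education. Duration effects (e.g. long-term unemployment
  scarring) are out of scope.
* A single period model pools all calendar years; no year covariate is
  fitted.
* Survey weights beyond a per-row weight, person-level frailty, and
  semi-Markov extensions are not implemented.
* Education is time-invariant (highest degree), as in the register design
  being emulated.
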