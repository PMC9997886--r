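---
title: "Simulating a Bayesian phase 2b platform trial in NASH"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating a Bayesian phase 2b platform trial in NASH}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

```{r setup}
library(platnash)
```

## The design being simulated

`platnash` simulates an exploratory phase 2b platform trial in
non-alcoholic steatohepatitis (NASH). The platform evaluates up to five
investigational treatments ("cohorts"), each consisting of a treatment arm
and a matched standard-of-care (SoC) control arm. Two cohorts open at week
0 and a new one enters every 24 weeks. Participants accrue at 6 per week,
are allocated evenly across cohorts open for enrollment, and within a
cohort are randomized 1:1 between arms in blocks of length two. Every
participant contributes two correlated binary outcomes, observed 52 weeks
after enrollment:

* **Endpoint 1** — resolution of NASH without worsening of fibrosis;
* **Endpoint 2** — at least one-stage fibrosis improvement without
  worsening of NASH.

Each cohort is analyzed when 50%, 75% and 100% of its planned sample size
(150 or 250 participants) have observed outcomes. At interim analyses a
cohort can stop early for efficacy (graduate) or futility; at the final
analysis a cohort that does not graduate stops for futility. Optionally,
control participants of other cohorts who enrolled while the index cohort
was enrolling ("concurrent controls") are pooled into its control group at
analyses.

## Correlated binary endpoints

The joint distribution of the two binary endpoints in one arm is a
bivariate Bernoulli with cell probabilities $p_{00}, p_{01}, p_{10},
p_{11}$ (indexed endpoint 1, endpoint 2). The package offers the four
standard constructions:

1. **Direct** (`joint_spec_direct()`): fix three cells, the fourth follows.
2. **Sensitivity/specificity** (`joint_spec_sens_spec()`): fix one marginal
   and the conditional agreement rates of one endpoint predicting the
   other; valid for any inputs in $[0,1]$.
3. **Phi correlation** (`joint_spec_phi()`): fix both marginals and the
   Pearson correlation
   $\phi = (p_{11} - p_{1\cdot}p_{\cdot 1}) / \sqrt{p_{0\cdot}p_{1\cdot}p_{\cdot 0}p_{\cdot 1}}$.
   For fixed marginals $\phi$ is only attainable inside the interval
   returned by `phi_bounds()`; out-of-range values are rejected with the
   attainable interval in the message.
4. **Latent bivariate normal** (`joint_spec_latent()`): fix both marginals
   and a latent correlation $\rho$; each endpoint succeeds when its
   standard-normal latent variable exceeds the quantile of its failure
   probability. This is the construction the trial engine uses, because a
   triplet (rate, rate, $\rho$) is easy to elicit from clinical teams and
   is valid for all $\rho \in (-1, 1)$.

A subtlety worth remembering: the achieved binary correlation $\phi$ is a
nonlinear, marginal-dependent function of $\rho$ (`rho_to_phi()`), equal to
$\rho$ only in sign and roughly attenuated otherwise; the full range
$[0, 1]$ is achievable only when both marginals are $0.5$.

```{r}
phi_bounds(0.3, 0.4)
rho_to_phi(0.3, 0.4, 0.7)
```

**Numerical choices.** Quadrant masses of the latent construction are
computed with `mvtnorm`'s bivariate-normal CDF at absolute tolerance
`1e-10`; the remaining cells come from the marginals by
inclusion–exclusion, so the requested marginals are preserved exactly. The
thresholds are the normal quantiles of the *failure* probabilities — the
unique choice that fixes the stated marginals. Cell values within `1e-12`
of $[0,1]$ are clipped; larger violations raise an error. Sampling uses
one four-cell multinomial draw per participant (distributionally identical
to thresholding latent normal draws, and faster). If a marginal rate is
exactly 0 or 1 the engine bypasses the copula entirely, because the joint
distribution is then uniquely the product table.

## Decision rules

All decisions are driven by one posterior quantity. With independent Beta
posteriors for the treatment ($\pi_E$) and control ($\pi_S$) response rate
of an endpoint, `prob_exceeds_by()` computes

$$P(\pi_E > \pi_S + \delta \mid D) = \int_0^{1-\delta} f_S(u)\,
  \bigl[1 - F_E(u + \delta)\bigr]\, du,$$

by 256-node Gauss–Legendre quadrature restricted to the effective support
of $f_S$ (absolute error well below $10^{-6}$; verified in the tests
against adaptive quadrature and Monte Carlo). Every arm and endpoint uses
a flat Beta(1, 1) prior, updated conjugately from the observed success
counts. Because a decision is a pure function of the four Beta parameters
and $\delta$, results are memoized, which makes $10^4$-replicate runs
cheap.

**Efficacy** is graded into three *evidence levels* per endpoint, applied
conjunctively — requiring level 3 means levels 1–3 must all hold
($\delta_1 < \delta_2 < \delta_3$ with $\gamma_1 > \gamma_2 > \gamma_3$):

| Level | Endpoint 1 margin | Endpoint 2 margin | Confidence |
|-------|-------------------|-------------------|------------|
| 1     | 0                 | 0                 | 95%        |
| 2     | 0.30              | 0.175             | 85%        |
| 3     | 0.40              | 0.25              | 60%        |

The same margins and confidences apply at interim and final analyses.
Level 1 with a flat prior gives approximately $1 - \gamma_1 = 5\%$
one-sided frequentist type I error per endpoint.

**Futility** applies only at interims: an endpoint is futile when
$P(\pi_E > \pi_S + \delta_F) < \gamma_F$, with margins $\delta_F = 0.25$
(endpoint 1) and $0.10$ (endpoint 2) and thresholds $\gamma_F = 0.20$ at
the first and $0.30$ at the second interim.

**Combination.** Following the FDA's "OR" recommendation, a cohort
graduates when *either* endpoint clears all required evidence levels, and
stops for futility only when *both* endpoints are futile. At the final
analysis, not graduating is itself a futility stop, so no futility gate is
parameterized there. Efficacy is evaluated before futility; with the
default parameters a simultaneous GO and STOP is impossible (for each
endpoint some required efficacy level dominates the futility gate), and
`decision_rule_set()` warns at construction whenever a parameterization
loses that guarantee — for example the level-1-only rule set. The strict
inequalities of the rules (`>` $\gamma$, `<` $\gamma_F$) follow the
design's formal definition; at floating-point resolution the distinction
from weak inequalities is untestable and purely conventional. An
"AND" efficacy combiner (both endpoints) is available via
`decision_rule_set(efficacy_combiner = "all")` but is not exercised by the
defaults.

```{r}
data <- list(
  list(treatment = arm_counts(60, 75), control = arm_counts(8, 75)),
  list(treatment = arm_counts(15, 75), control = arm_counts(15, 75)))
evaluate_cohort(data, default_decision_rules(), analysis_index = 1,
                is_final = FALSE)
```

## The trial engine

`run_platform()` advances a weekly clock. Within a week events are
ordered: outcomes whose 52-week observation lag has elapsed mature first,
then analyses fire (in cohort-entry order) for every cohort whose own
observed-outcome count has reached $\lceil f_T \cdot N \rceil$ (113 of 150
for the 75% look, for example), then the week's six arrivals are allocated.
This ordering means an analysis sees all outcomes matured up to and
including its week, and no participant is enrolled into a cohort that was
stopped the same week.

Design decisions the engine makes explicit:

* **Deterministic accrual.** Six participants per week, exactly: the design
  documents describe the accrual rate as an approximation without a
  distribution, and fixed accrual reproduces the constant-enrollment
  arithmetic of the 150-participant design (750 participants in every
  replicate).
* **Fixed cohort calendar.** Entry weeks (0, 0, 24, 48, 72 by default) do
  not react to early stops; the platform always evaluates all five
  treatments.
* **Allocation.** The week's arrivals are split as evenly as possible
  across open cohorts; the remainder rotates via a persistent round-robin
  pointer so long-run allocation is equal. Arrivals exceeding total open
  capacity are lost, not queued (with default parameters this never
  happens).
* **Concurrent-control window.** A control participant of another cohort
  is pooled if their enrollment week lies within the index cohort's own
  enrollment window — first enrollment week to last (or to the current week
  while the cohort is still enrolling) — and their outcome is observed by
  the analysis week. Both clauses are interpretations of "while
  randomization is ongoing"; the tests pin them down with a brute-force
  ledger filter.
* **Zero decision lag.** An interim decision takes effect in the week its
  triggering count is reached; enrollment into other cohorts proceeds the
  same week.
* **Reproducibility.** `simulate_platform()` derives one sub-seed per
  replicate from the master seed, so replicates are order-independent and
  the full run is bit-reproducible from its manifest.

A linear calendar drift of all response probabilities
(`time_trend_per_week`) is supported and validated against the enrollment
horizon, but the default — like the design's base case — is zero.

```{r}
cfg <- platform_config(trt_rates = c(0.55, 0.55), rho = 0.3, seed = 7)
set.seed(7)
run_platform(cfg)
```

## Operating characteristics

`summarize_oc()` pools cohort decisions across replicates — under a single
treatment-effect scenario all five cohorts are exchangeable, so the success
probability uses $5 \times$ `n_sims` evaluations and its binomial standard
error reflects that pooled count. Trial duration (week of the last
decision) and total enrollment are averaged per replicate;
`participants_saved` is the planned maximum minus mean enrollment.
`scenario_grid()` builds the Cartesian product of scenario axes with
deterministic per-scenario seeds; sharing a base seed across scenarios
gives common random numbers, which the monotonicity tests (success
probability non-increasing in required evidence level and in $\rho$,
non-decreasing in effect size) exploit. That matched-seed device sharpens
comparisons between scenarios; it does not claim to replicate any
particular independent run.

## What the generator does and does not emulate

The synthetic-data generator *is* the study: all trial data are internal
draws from the latent-Gaussian bivariate Bernoulli model at configured
rates. It faithfully represents the design assumptions — fixed accrual,
homogeneous response rates across cohorts and calendar time (by default),
no dropout, complete paired biopsies at week 52, exchangeable cohorts. It
does not emulate features real NASH trials have: over- or under-accrual,
missing or unreadable biopsies, site and reader variability,
population drift, or treatment effects that differ between cohorts.
Passing operating-characteristic checks therefore validates the design
arithmetic under its stated assumptions, not the design's behaviour on
real data.

One caution inherited from the source material: an illustrative
expected-responder head count sometimes quoted for rates 30%/40% at
$\rho = -0.3$ / $0.7$ (69 and 53 "at least one endpoint" responders per
100) is inconsistent with the quadrant probabilities of the latent model,
which give roughly 62 and 47; the package's oracles side with the quadrant
arithmetic, and those head counts are deliberately not used as tests.

## Problem sizes used by the bundled checks

The package's own simulation studies default to 10,000 replicates per
scenario. The bundled test suite and the reproduction script
(`scripts/acceptance.R`) run the deterministic checks in full and the
platform-level scenarios at 1,200–3,000 replicates (6,000–15,000 pooled
cohort evaluations) — sizes chosen so that four Monte-Carlo standard
errors remain well inside the tolerance of every published figure they are
compared against, while a complete run stays desk-scale. The calibration
check of the level-1 rule runs its full 10,000 replicates, which is cheap
because the decision boundary over success counts is tabulated once.

## Known limitations

* Only two endpoints and a Gaussian copula; no covariates beyond treatment.
* No response-adaptive randomization, non-concurrent controls, shrinkage
  across cohorts, or multiplicity adjustment across cohorts — all outside
  the design being simulated.
* The futility thresholds are tied to the two-interim layout; configuring
  a different number of interims requires supplying matching
  `futility_gate()` thresholds.
* Between-scenario comparisons with matched seeds are sharper than the
  independent-runs comparisons a regulator would see; both are available.
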