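---
title: "Parametric Weibull multistate models for disease progression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Parametric Weibull multistate models for disease progression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msweib)
```

## The model

`msweib` analyses event histories on a directed multistate topology under
a time-inhomogeneous Markov assumption. The default topology is the
clinical course of prefibrotic primary myelofibrosis (pre-PMF): patients
start in pre-PMF (state 1) and can progress to overt PMF (state 2),
transform to acute myeloid leukemia (AML, state 3), or die (state 4, the
only absorbing state), with six allowed transitions
1→2, 1→3, 1→4, 2→3, 2→4, 3→4.

Each transition $k: a \to b$ carries its own Weibull
proportional-hazards intensity on the *clock-forward* time scale $t$
(years since diagnosis):

$$h_k(t \mid x) = \lambda_k \gamma_k t^{\gamma_k - 1}
  \exp(x^\top \beta_k), \qquad
  H_k(t \mid x) = \lambda_k t^{\gamma_k} \exp(x^\top \beta_k),$$

with shape $\gamma_k > 0$, rate-scale $\lambda_k > 0$ and log hazard
ratios $\beta_k$. Covariates are fixed at baseline. Because all hazards
share the diagnosis clock, a sojourn that starts in state $a$ at time
$t_0 > 0$ enters the risk sets of the transitions out of $a$ late: this
is delayed entry (left truncation), and each stacked at-risk interval
$(t_0, t_1]$ with event indicator $d$ contributes

$$\ell = d \log h_k(t_1 \mid x) -
  \left[H_k(t_1 \mid x) - H_k(t_0 \mid x)\right]$$

to the transition-specific log-likelihood. Transitions are fitted
independently; no parameters are shared across transitions. A
semi-Markov (clock-reset) stacking is available in
`build_long_format(clock = "reset")` but is not used by the replication
pipeline, which follows the Markov formulation.

## Estimation

`fit_transition()` maximizes the likelihood over
$(\log\lambda, \log\gamma, \beta)$ by BFGS with the analytic score,
started at the exponential solution ($\gamma = 1$,
$\lambda = \text{events}/\text{exposure}$, $\beta = 0$). If the gradient
check fails (max absolute score above $10^{-5}$ on the scale of the
log-likelihood), up to five restarts jitter $\log\gamma$ with a
deterministic stream, so fits are reproducible. The covariance is the
inverse observed information from a numerical Hessian at the optimum; a
singular Hessian flags the covariance unavailable rather than failing
the fit. Wald hazard-ratio tables use
$\exp(\beta \pm z_{1-\alpha/2}\,\mathrm{SE})$ and two-sided normal
p-values without multiplicity correction. Model families are compared by
$\mathrm{AIC} = -2\ell + 2k$ with $k$ the number of free parameters
(two baseline parameters plus the coefficients).

## Prediction

Transition probabilities $P_{ab}(s, t)$ solve the Kolmogorov forward
equation $\partial_t P(s, t) = P(s, t) Q(t)$ from $P(s, s) = I$, where
$Q(t)$ holds the fitted intensities off-diagonal and negative row sums
on the diagonal. Integration uses `deSolve::lsoda` with `rtol = 1e-10`,
`atol = 1e-12`. Numerical guards:

* when any $\gamma_k < 1$ the hazard is singular at $t = 0$, so
  integration (and the default grid, 401 points over 0–25 years) starts
  at $\varepsilon = 10^{-6}$ years;
* tiny negative excursions (magnitude up to $10^{-9}$) are clipped to
  zero and rows renormalized; larger violations raise an error instead
  of being hidden.

The Monte Carlo predictor draws whole Markov paths: in state $a$ at time
$s$, the next event time solves
$\sum_{k \in \mathrm{out}(a)} [H_k(t) - H_k(s)] = E$, $E \sim
\mathrm{Exp}(1)$, by 60 bisection halvings of $[s, \text{horizon}]$
(resolution far below $10^{-8}$ years; an exceedance of the horizon
means censoring there, so no bracket growth beyond it is needed), and
the destination is drawn proportional to the cause-specific hazards at
the event time. The exact same sampler generates synthetic cohorts, so
the generator and the predictor cannot drift apart.

State occupation probabilities are the initial-state row of $P(0, t)$.
For cohort-level curves the package *population-averages*: it averages
the per-profile curves over the cohort's covariate rows (or exactly over
the $2^m$ profile distribution via `expected_occupation()`). A single
reference profile is available through the `x` argument. The published
figures do not state which convention they used; population averaging
was chosen as the default because it is the quantity a registry-level
stacked plot displays. For transitions out of intermediate states the
conditioning time `s` is exposed as a parameter; the pipeline uses the
mean observed entry time into the conditioning state.

## Nonparametric oracle

`nelson_aalen()` and `aalen_johansen()` implement the standard
counting-process estimators on the same stacked rows, honouring delayed
entry ($Y(t) = \#\{t_0 < t \le t_1\}$, so a censoring tied with an event
remains at risk). The Aalen–Johansen product integral
$\prod (I + \Delta A(t))$ keeps rows summing to one exactly and reduces
to one minus Kaplan–Meier in the two-state case (verified against
`survival::survfit`, which also cross-checks the full multistate
estimator). These estimators are a model-free yardstick for the
parametric predictions; they are exported but deliberately not part of
the replication report.

## The synthetic cohort generator

No public patient-level data exist for the 382-patient registry the
default model emulates, so `registry_like_config()` defines a synthetic
study population:

* **Topology and transition mix.** The published counts
  (58, 18, 66, 10, 14, 25 events over transitions 1–6; 15.2%, 4.7% and
  17.3% direct transitions) anchor the baseline rates. The rates were
  calibrated once by a multiplicative fixed point on simulated expected
  counts at $n = 200{,}000$ per iteration (`scripts/calibrate.R`; log in
  `inst/extdata/calibration.json`) and shipped as constants.
* **Shapes.** $\gamma = (1.0, 0.9, 1.2, 0.6, 1.3, 1.5)$ encode the
  qualitative time course reported for the cohort: leukemic risk out of
  overt PMF concentrated in the first years ($\gamma_4 < 1$), mortality
  accelerating with time overall and especially after progression
  ($\gamma_3, \gamma_5, \gamma_6 > 1$). The published analysis reports
  no baseline parameters, so these are modelling choices, fixed before
  calibration of the rates.
* **Covariates.** Independent Bernoulli draws. Prevalences: grade-1
  fibrosis 0.58 and HMR 0.28 are published; age > 65 (0.35),
  WBC > 15×10⁹/L (0.20) and anemia (0.25) are plausible assumptions
  (only the prevalence of age ≥ 60, 45%, is published). Effects are the
  published multivariable hazard ratios (see `?registry_like_config`),
  zero elsewhere; treatment indicators (chemotherapy 0.77, antiplatelets
  0.72, anticoagulants 0.15) and the mutation-data-availability flag
  (132/382) are carried with zero effect so that the fitting pipeline
  can adjust for them as the published models did.
* **Censoring.** Administrative horizon 32.6 years (the longest
  follow-up reported) plus exponential dropout with rate
  $\log 2 / 6.89$, so the median *potential* follow-up — the
  reverse-Kaplan–Meier quantity usually quoted as "median follow-up" —
  is the published 6.89 years. Observed time in study is shorter
  because deaths truncate it.

What the generator does **not** emulate: covariate correlations (the
registry's joint distribution is unpublished), continuous laboratory
values underlying the dichotomizations, time-varying treatment, and
between-centre heterogeneity. Recovery and calibration tests on this
generator therefore validate the estimation and prediction machinery
under the model's own assumptions; they cannot validate the Markov or
proportional-hazards assumptions against the real registry.

## Replication pipeline

`run_registry_analysis()` chains counting, stacking, per-transition fits of
a clinical family (dichotomized risk factors adjusted for three
treatment indicators) and a mutational family (HMR; fitted on the
mutation-informative subcohort, emulating 132 of 382 patients), the AIC
comparison, and ODE plus simulated probability curves. Because the two
families are fitted on different subcohorts, AICs are not directly
comparable across families; the pipeline therefore also refits the
clinical family on the subcohort (`clinical_subcohort`) so the
comparison is available at equal $n$, and reports all three. Transitions
with zero events are skipped and flagged, not fatal. Covariate models
for transitions 4–6 are unreported in the source analysis, so the
pipeline fits baseline-only hazards there.

Degenerate inputs are rejected rather than repaired: zero-length
sojourns (`t_start == t_stop`), non-increasing trajectory times, and
jumps not in the transition set all raise errors naming the subject. A
transition recorded at the same instant as censoring counts as the
transition; regression to an earlier disease stage is not representable
by design.

## Problem sizes used in the shipped checks

Unit and property tests run on cohorts of a few hundred to a few
thousand subjects; the deeper simulation checks use 200 replicates of
$n = 5000$ for hazard-ratio recovery and Wald coverage, 100,000 paths
per starting state for the Monte Carlo/ODE cross-check, $n = 10{,}000$
with 30 bootstrap resamples for the Aalen–Johansen comparison, and 500
seeds of $n = 382$ for the calibration reproduction. These sizes give
Monte Carlo standard errors comfortably inside the tolerances tested
while keeping a full run in the minutes range.

## Known limitations

* Confidence bands for predicted probabilities are not provided (the
  source analysis reports none and the delta method over the ODE
  solution is out of scope).
* The Markov assumption is structural: sojourn-time effects (e.g., time
  since progression) are only representable through the shared
  diagnosis clock.
* Fits with very few events and several covariates (typical of the
  AML transition at registry size) can have unstable Wald intervals;
  the pipeline reports them as fitted, as the source analysis did,
  but the monotone-likelihood caveat applies.
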