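# msweib

Parametric Weibull Markov multistate survival models, built around the
clinical course of prefibrotic primary myelofibrosis (pre-PMF): patients
are diagnosed in pre-PMF and may progress to overt PMF, transform to
acute myeloid leukemia (AML), or die, along six allowed transitions
(1→2, 1→3, 1→4, 2→3, 2→4, 3→4; death is absorbing). The package is for
biostatisticians modelling disease progression with intermediate states,
where competing-risks-aware transition estimates — not single-endpoint
Kaplan–Meier curves — are the quantity of interest.

Each transition k: a→b gets its own Weibull proportional-hazards
intensity on the time-since-diagnosis clock,

    h_k(t | x) = lambda_k * gamma_k * t^(gamma_k - 1) * exp(x' beta_k),

fitted by maximum likelihood on stacked at-risk intervals with delayed
entry (left truncation). From the fitted intensity matrix Q(t) the
package predicts transition probabilities P_ab(s, t) by integrating the
Kolmogorov forward equation dP/dt = P·Q(t), and by simulating Markov
paths whose next-event times invert the total cumulative hazard.
Covariate families (clinical vs mutational, e.g. high-molecular-risk
mutation carriership) are compared per transition by AIC. Nonparametric
Nelson–Aalen and Aalen–Johansen estimators provide a model-free
cross-check, and a calibrated synthetic cohort generator stands in for
the private 382-patient registry the default configuration emulates.

## Worked example

```r
library(msweib)

space <- pmf_state_space()
cohort <- generate_cohort(registry_like_config(), seed = 42)

count_transitions(cohort, space)$transitions
#>   transition from to  n  pct
#> 1          1    1  2 56 14.7
#> 2          2    1  3 16  4.2
#> 3          3    1  4 64 16.8
#> 4          4    2  3  9  2.4
#> 5          5    2  4 15  3.9
#> 6          6    3  4 23  6.0

long <- build_long_format(cohort, space)          # stacked, clock-forward
fit  <- fit_transition(long, 3, c("age_gt65", "wbc_gt15"))
fit
#> Weibull PH fit, transition 3: shape 0.9467, rate 0.009444,
#>   logLik -250.129, AIC 508.26
#>   covariate       HR    lower    upper            p
#> 1  age_gt65 8.311266 4.841628 14.26734 1.580072e-14
#> 2  wbc_gt15 3.295377 1.961436  5.53651 6.642890e-06

model <- fit_multistate(long, space)
occ <- state_occupation(model, c(5, 10, 20), newdata = cohort)
round(occ$occupation, 3)
#>      pre-PMF overt PMF   AML death
#> [1,]   0.706     0.098 0.006 0.190
#> [2,]   0.550     0.122 0.003 0.325
#> [3,]   0.357     0.107 0.001 0.535
```

One synthetic 382-patient cohort reproduces the expected transition mix
up to sampling noise (the expected direct percentages are 15.2, 4.7 and
17.3). The fitted death-transition hazard ratios recover the generating
values (age > 65: 6.53, WBC > 15: 3.49) within the sampling error of 64
events, and the population-averaged occupation probabilities show the
characteristic course: a majority still event-free at 10 years and
deaths approaching 60% by 20 years.

`run_registry_analysis(cohort, out_dir = "report")` runs the whole
replication pipeline (counts, clinical vs mutational fits per direct
transition, AIC table, ODE and simulated curves) and writes CSV/JSON
outputs. A thin command-line wrapper with `simulate`, `counts`, `fit`,
`predict` and `analyze` subcommands is installed at
`inst/cli/msweib.R`.

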