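#' Default synthetic pre-PMF cohort configuration
#'
#' A calibrated stand-in for a 382-patient pre-PMF registry followed for a
#' median of about 6.9 years. Binary risk factors are drawn independently
#' at published or assumed prevalences; their per-transition log hazard
#' ratios are the published multivariable estimates where available
#' (evolution to overt PMF: anemia 2.18, grade-1 fibrosis 3.20, HMR 3.15;
#' evolution to AML: age>65 10.3, WBC>15 4.80; death: age>65 6.53,
#' WBC>15 3.49, HMR 4.62) and zero elsewhere. Treatment indicators and the
#' mutation-data-availability flag are carried as inert columns. Baseline
#' Weibull rates were calibrated once (see `scripts/calibrate.R`, log in
#' `inst/extdata/calibration.json`) so that expected per-transition event
#' counts match the observed transition mix (58, 18, 66, 10, 14, 25 events
#' out of 382); shapes encode the qualitative hazard evolution (early-then
#' -waning leukemic risk, accelerating mortality after progression).
#'
#' Prevalences of age>65, WBC>15 and anemia among the modelled cohort are
#' not published and are plausible assumptions (0.35, 0.20, 0.25); grade-1
#' fibrosis (0.58) and HMR (0.28) are published.
#'
#' @param n_subjects Cohort size (default 382).
#' @param seed Default generation seed.
#' @return A `cohort_config`.
#' @export
registry_like_config <- function(n_subjects = 382, seed = 20201014) {
  K6 <- function(...) {
    v <- numeric(6)
    args <- list(...)
    for (k in names(args)) v[as.integer(k)] <- args[[k]]
    v
  }
  cohort_config(
    n_subjects = n_subjects,
    space = pmf_state_space(),
    #             1->2   1->3   1->4   2->3   2->4   3->4
    shapes = c(1.00, 0.90, 1.20, 0.60, 1.30, 1.50),
    rates = registry_like_rates(),
    covariates = list(
      age_gt65 = list(prevalence = 0.35,
                      loghr = K6(`2` = log(10.3), `3` = log(6.53))),
      wbc_gt15 = list(prevalence = 0.20,
                      loghr = K6(`2` = log(4.80), `3` = log(3.49))),
      anemia = list(prevalence = 0.25, loghr = K6(`1` = log(2.18))),
      fibrosis_g1 = list(prevalence = 0.58, loghr = K6(`1` = log(3.20))),
      hmr = list(prevalence = 0.28,
                 loghr = K6(`1` = log(3.15), `3` = log(4.62))),
      chemo = list(prevalence = 0.77, loghr = K6()),
      antiplatelet = list(prevalence = 0.72, loghr = K6()),
      anticoagulant = list(prevalence = 0.15, loghr = K6()),
      mut_informative = list(prevalence = 132 / 382, loghr = K6())),
    admin_horizon = 32.6,
    dropout_rate = log(2) / 6.89,
    seed = seed)
}

# Baseline rate-scales from the shipped calibration run (multiplicative
# fixed-point on simulated expected event counts, n = 200000 per
# iteration; see scripts/calibrate.R).
registry_like_rates <- function() {
  c(0.00630834, 0.00178708, 0.00352672, 0.11141213, 0.01720873, 0.31036343)
}

#' True-parameter predictive model of a cohort configuration
#'
#' Packages the generator's Weibull parameters as an `msm_fit`, so that
#' ODE or simulation predictions under the true data-generating model can
#' be compared with fitted or nonparametric estimates. Only covariates
#' with a nonzero log-HR on a transition enter that transition's
#' coefficient vector.
#'
#' @param config A `cohort_config`.
#' @return An `msm_fit`.
#' @export
config_model <- function(config) {
  K <- nrow(config$space$transitions)
  fits <- lapply(seq_len(K), function(k) {
    beta <- vapply(config$covariates, function(cv) cv$loghr[k], 0)
    beta <- beta[beta != 0]
    list(shape = config$shapes[k], rate = config$rates[k], beta = beta)
  })
  msm_fit(config$space, fits)
}

#' Exact covariate-profile distribution of a configuration
#'
#' Enumerates the 2^m profiles of the covariates that carry a nonzero
#' effect, with their joint probabilities under independent Bernoulli
#' sampling. Used for exact population-averaged predictions.
#'
#' @param config A `cohort_config`.
#' @return List with `profiles` (data.frame) and `weights`.
#' @export
config_profiles <- function(config) {
  active <- names(Filter(function(cv) any(cv$loghr != 0),
                         config$covariates))
  if (!length(active))
    return(list(profiles = data.frame()[1, , drop = FALSE], weights = 1))
  grid <- do.call(expand.grid, stats::setNames(
    rep(list(0:1), length(active)), active))
  w <- rep(1, nrow(grid))
  for (nm in active) {
    p <- config$covariates[[nm]]$prevalence
    w <- w * ifelse(grid[[nm]] == 1, p, 1 - p)
  }
  list(profiles = grid, weights = w)
}

#' Population-averaged state occupation under a configuration's true model
#'
#' @param config A `cohort_config`.
#' @param times Prediction grid.
#' @return An `occupation_curves` object (exact profile-weighted average).
#' @export
expected_occupation <- function(config, times) {
  model <- config_model(config)
  pr <- config_profiles(config)
  a <- match(first_nonabsorbing(config$space), config$space$states)
  occ <- 0
  for (j in seq_len(nrow(pr$profiles))) {
    x <- unlist(pr$profiles[j, , drop = TRUE])
    pc <- transition_probabilities(model, 0, times, x)
    occ <- occ + pr$weights[j] * pc$P[, a, ]
  }
  occ <- matrix(occ, nrow = length(times),
                dimnames = list(NULL, config$space$labels))
  structure(list(times = times, occupation = occ,
                 bands = t(apply(occ, 1, cumsum)),
                 initial_state = first_nonabsorbing(config$space),
                 method = "ode", space = config$space),
            class = "occupation_curves")
}
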