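# Shared fixtures, all built in code.

two_state_space <- function() {
  state_space(1:2, c("alive", "dead"), c(FALSE, TRUE), cbind(1, 2))
}

# msm_fit with bare (shape, rate, beta) parameter lists
param_model <- function(space, shapes, rates, betas = NULL) {
  K <- nrow(space$transitions)
  fits <- lapply(seq_len(K), function(k)
    list(shape = shapes[k], rate = rates[k],
         beta = if (is.null(betas)) stats::setNames(numeric(0),
                                                    character(0))
               else betas[[k]]))
  msm_fit(space, fits)
}

# all-exponential 4-state model with fixed rates (hazards constant in t)
exp_pmf_model <- function(rates = c(0.06, 0.02, 0.05, 0.15, 0.12, 0.4)) {
  param_model(pmf_state_space(), shapes = rep(1, 6), rates = rates)
}

# small hand-written cohort: one censored, one two-jump, one direct death
toy_cohort <- function() {
  data.frame(
    subject_id = c("a", "b", "c"),
    x = c(0, 1, 0),
    time_overtPMF = c(NA, 3, NA),
    time_AML = c(NA, NA, NA),
    time_death = c(NA, 7, 4),
    time_censor = c(5, NA, NA))
}

# no-covariate Weibull cohort config on the 4-state space
plain_weibull_config <- function(n = 1000, seed = 11,
                                 admin_horizon = 30, dropout_rate = 0.08) {
  cohort_config(n_subjects = n, space = pmf_state_space(),
                shapes = c(1.0, 0.9, 1.2, 0.6, 1.3, 1.5),
                rates = c(0.012, 0.004, 0.008, 0.15, 0.03, 0.35),
                admin_horizon = admin_horizon,
                dropout_rate = dropout_rate, seed = seed)
}

# independent refining grid search over (log lambda, log gamma, beta)
grid_search_mle <- function(t_start, t_stop, status, X, center,
                            width = 1.5, zoom = 6, n_grid = 11) {
  p <- center
  for (z in seq_len(zoom)) {
    grids <- lapply(seq_along(p), function(j)
      seq(p[j] - width, p[j] + width, length.out = n_grid))
    best <- -Inf
    cells <- do.call(expand.grid, grids)
    for (r in seq_len(nrow(cells))) {
      cand <- as.numeric(cells[r, ])
      ll <- weibull_ph_loglik(cand, t_start, t_stop, status, X)
      if (ll > best) {
        best <- ll
        p <- cand
      }
    }
    width <- width * 2.2 / (n_grid - 1)   # shrink around the best cell
  }
  list(par = p, loglik = best)
}
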