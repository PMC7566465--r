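test_that("the exponential special case has the closed-form likelihood", {
  # shape 1, rate 0.1, one interval (0, 2] with an event
  ll <- weibull_ph_loglik(c(log(0.1), 0), 0, 2, 1)
  expect_equal(ll, log(0.1) - 0.2)
})

test_that("degenerate intervals and bad parameters are rejected", {
  expect_error(weibull_ph_loglik(c(0, 0), 2, 2, 1), "t_start < t_stop")
  expect_error(weibull_ph_loglik(c(NA, 0), 0, 2, 1), "non-finite")
  expect_error(weibull_ph_loglik(c(0, 0), -1, 2, 1), "t_start")
})

test_that("the likelihood matches a quadrature oracle on random data", {
  set.seed(101)
  for (rep in 1:5) {
    n <- 12
    t0 <- round(runif(n, 0, 2), 3)
    t1 <- t0 + round(runif(n, 0.1, 3), 3)
    d <- rbinom(n, 1, 0.6)
    X <- cbind(runif(n), rbinom(n, 1, 0.5))
    par <- c(log(runif(1, 0.05, 0.5)), log(runif(1, 0.6, 1.6)),
             rnorm(2, 0, 0.5))
    lam <- exp(par[1]); gam <- exp(par[2]); eta <- drop(X %*% par[3:4])
    oracle <- sum(vapply(seq_len(n), function(i) {
      h <- function(t) lam * gam * t^(gam - 1) * exp(eta[i])
      H <- stats::integrate(h, t0[i], t1[i], rel.tol = 1e-12)$value
      d[i] * log(h(t1[i])) - H
    }, 0))
    expect_equal(weibull_ph_loglik(par, t0, t1, d, X), oracle,
                 tolerance = 1e-8)
  }
})

test_that("analytic score matches numerical differentiation", {
  set.seed(7)
  t0 <- c(0, 0, 1, 2); t1 <- c(2, 3, 4, 5); d <- c(1, 0, 1, 1)
  X <- cbind(c(1, 0, 1, 0))
  par <- c(-2, 0.2, 0.4)
  g <- weibull_ph_score(par, t0, t1, d, X)
  num <- vapply(seq_along(par), function(j) {
    h <- 1e-6
    pp <- pm <- par; pp[j] <- pp[j] + h; pm[j] <- pm[j] - h
    (weibull_ph_loglik(pp, t0, t1, d, X) -
       weibull_ph_loglik(pm, t0, t1, d, X)) / (2 * h)
  }, 0)
  expect_equal(g, num, tolerance = 1e-5)
})

test_that("with shape fixed at 1 and no covariates the MLE is
           events/exposure", {
  set.seed(21)
  long <- data.frame(transition = 1, t_start = runif(40, 0, 1))
  long$t_stop <- long$t_start + runif(40, 0.2, 4)
  long$status <- rbinom(40, 1, 0.5)
  long$status[1] <- 1L
  f <- fit_transition(long, 1, fixed_shape = 1)
  expect_equal(f$shape, 1)
  expect_equal(f$rate,
               sum(long$status) / sum(long$t_stop - long$t_start),
               tolerance = 1e-7)
  expect_equal(f$npar, 1)
})

test_that("the optimizer agrees with an independent refining grid search
           on a toy dataset", {
  set.seed(33)
  n <- 20
  x <- rbinom(n, 1, 0.5)
  t1 <- rweibull(n, shape = 1.4, scale = (0.2 * exp(0.8 * x))^(-1 / 1.4))
  cens <- runif(n, 0.5, 6)
  long <- data.frame(transition = 1, t_start = 0,
                     t_stop = round(pmin(t1, cens), 4),
                     status = as.integer(t1 <= cens), x = x)
  f <- fit_transition(long, 1, "x")
  gs <- grid_search_mle(long$t_start, long$t_stop, long$status,
                        cbind(long$x), center = unname(f$par))
  expect_lt(max(abs(unname(f$par) - gs$par)), 1e-4)
  expect_gte(f$loglik, gs$loglik - 1e-8)
})

test_that("fits agree with flexsurv's Weibull PH on simulated data", {
  skip_if_not_installed("flexsurv")
  skip_if_not_installed("survival")
  set.seed(55)
  n <- 400
  x <- rbinom(n, 1, 0.4)
  t1 <- rweibull(n, shape = 0.8, scale = (0.1 * exp(0.7 * x))^(-1 / 0.8))
  cens <- runif(n, 1, 15)
  long <- data.frame(transition = 1, t_start = 0,
                     t_stop = pmin(t1, cens),
                     status = as.integer(t1 <= cens), x = x)
  f <- fit_transition(long, 1, "x")
  fs <- flexsurv::flexsurvreg(
    survival::Surv(t_stop, status) ~ x, data = long, dist = "weibullPH")
  expect_equal(f$shape, unname(fs$res["shape", "est"]), tolerance = 1e-4)
  expect_equal(f$rate, unname(fs$res["scale", "est"]), tolerance = 1e-4)
  expect_equal(unname(f$coef), unname(fs$res["x", "est"]),
               tolerance = 1e-4)
  expect_equal(f$loglik, fs$loglik, tolerance = 1e-6)
  expect_equal(sqrt(diag(f$vcov))[["x"]], unname(fs$res["x", "se"]),
               tolerance = 1e-3)
})

test_that("delayed-entry intervals carry the left-truncation correction", {
  skip_if_not_installed("flexsurv")
  skip_if_not_installed("survival")
  set.seed(77)
  n <- 300
  entry <- runif(n, 0, 2)
  raw <- entry + rweibull(n, 1.3, scale = 3)
  cens <- entry + runif(n, 0.5, 8)
  long <- data.frame(transition = 1, t_start = entry,
                     t_stop = pmin(raw, cens),
                     status = as.integer(raw <= cens))
  f <- fit_transition(long, 1)
  fs <- flexsurv::flexsurvreg(
    survival::Surv(t_start, t_stop, status) ~ 1, data = long,
    dist = "weibullPH")
  expect_equal(f$shape, unname(fs$res["shape", "est"]), tolerance = 1e-4)
  expect_equal(f$rate, unname(fs$res["scale", "est"]), tolerance = 1e-4)
})

test_that("hazard ratio tables follow the Wald construction", {
  f <- structure(list(transition = 1, shape = 1, rate = 0.1,
                      coef = c(x = 0), par = c(log_lambda = log(0.1),
                                               log_gamma = 0, x = 0),
                      vcov = diag(c(0.1, 0.1, 0.25)), vcov_ok = TRUE,
                      loglik = -10, n_events = 5, n_rows = 10, npar = 3,
                      covariates = "x"), class = "weibull_ph")
  hr <- hazard_ratios(f)
  expect_equal(hr$HR, 1)
  expect_equal(hr$lower, exp(-qnorm(0.975) * 0.5), tolerance = 1e-6)
  expect_equal(hr$upper, exp(qnorm(0.975) * 0.5), tolerance = 1e-6)
  expect_equal(hr$p, 1)
  # vanishing SE collapses the interval onto the point estimate
  f$coef <- c(x = log(2))
  f$vcov <- diag(c(0.1, 0.1, 1e-24))
  hr <- hazard_ratios(f)
  expect_equal(hr$HR, 2)
  expect_equal(hr$lower, 2, tolerance = 1e-6)
  expect_equal(hr$upper, 2, tolerance = 1e-6)
  f$vcov_ok <- FALSE
  expect_error(hazard_ratios(f), "covariance unavailable")
})

test_that("AIC is -2 logLik + 2 (free parameters) and behaves on nested
           fits", {
  f <- structure(list(loglik = -100, npar = 2), class = "weibull_ph")
  expect_equal(AIC(f), 204)
  set.seed(88)
  long <- data.frame(transition = 1, t_start = 0,
                     t_stop = rweibull(150, 1.2, 4),
                     status = rep(1L, 150),
                     noise = rbinom(150, 1, 0.5))
  f0 <- fit_transition(long, 1)
  f1 <- fit_transition(long, 1, "noise")
  lr <- 2 * (f1$loglik - f0$loglik)
  expect_gte(lr, -1e-8)                      # monotone in added covariates
  expect_equal(AIC(f1) - AIC(f0), 2 - lr, tolerance = 1e-8)
})

test_that("rescaling the time unit transforms the rate deterministically
           and leaves shape, coefficients and fit quality unchanged", {
  set.seed(99)
  n <- 250
  x <- rbinom(n, 1, 0.5)
  t1 <- rweibull(n, 1.3, scale = (0.05 * exp(0.5 * x))^(-1 / 1.3))
  cens <- runif(n, 2, 20)
  long <- data.frame(transition = 1, t_start = 0,
                     t_stop = pmin(t1, cens),
                     status = as.integer(t1 <= cens), x = x)
  f_yr <- fit_transition(long, 1, "x")
  long_mo <- transform(long, t_stop = t_stop * 12)
  f_mo <- fit_transition(long_mo, 1, "x")
  expect_equal(f_mo$shape, f_yr$shape, tolerance = 1e-5)
  expect_equal(f_mo$coef, f_yr$coef, tolerance = 1e-5)
  expect_equal(f_mo$rate, f_yr$rate * 12^(-f_yr$shape), tolerance = 1e-5)
  # log-likelihoods differ by the Jacobian of the time change
  expect_equal(f_mo$loglik, f_yr$loglik - sum(long$status) * log(12),
               tolerance = 1e-6)
})

test_that("the returned optimum is a stationary point and zero-event
           transitions are refused", {
  set.seed(12)
  long <- data.frame(transition = 1, t_start = 0,
                     t_stop = rweibull(120, 0.9, 5),
                     status = rbinom(120, 1, 0.7))
  long$status[1] <- 1L
  f <- fit_transition(long, 1)
  g <- weibull_ph_score(unname(f$par), long$t_start, long$t_stop,
                        long$status)
  expect_lt(max(abs(g)) / max(1, abs(f$loglik)), 1e-5)
  long0 <- transform(long, status = 0L)
  expect_error(fit_transition(long0, 1), "zero events")
})

test_that("moderate-sample recovery: simulated effects are estimated
           within Monte Carlo error", {
  cfg <- cohort_config(
    n_subjects = 3000, space = two_state_space(),
    shapes = 1.3, rates = 0.05,
    covariates = list(age = list(prevalence = 0.35, loghr = log(2.5))),
    admin_horizon = 20, dropout_rate = 0.05, seed = 202)
  coh <- generate_cohort(cfg)
  long <- build_long_format(coh, cfg$space)
  f <- fit_transition(long, 1, "age")
  se <- sqrt(diag(f$vcov))
  expect_lt(abs(f$coef[["age"]] - log(2.5)), 3 * se[["age"]])
  expect_lt(abs(log(f$shape) - log(1.3)), 3 * se[["log_gamma"]])
})
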