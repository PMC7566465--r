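# Transition-specific Weibull proportional-hazards likelihood with delayed
# entry. Hazard h(t|x) = lambda * gamma * t^(gamma-1) * exp(x'beta),
# cumulative hazard H(t|x) = lambda * t^gamma * exp(x'beta). A row at risk
# over (t_start, t_stop] with event indicator d contributes
#   d * log h(t_stop|x) - [H(t_stop|x) - H(t_start|x)],
# the t_start term implementing left truncation on the clock-forward
# (Markov) time scale. Optimization is over (log lambda, log gamma, beta).

#' Weibull PH log-likelihood for one transition
#'
#' @param par Numeric vector `c(log_lambda, log_gamma, beta...)`.
#' @param t_start,t_stop Entry and exit times of each at-risk interval
#'   (years); `0 <= t_start < t_stop`.
#' @param status 0/1 event indicator at `t_stop`.
#' @param X Design matrix (rows match intervals), or NULL for no covariates.
#' @return The log-likelihood (scalar).
#' @export
weibull_ph_loglik <- function(par, t_start, t_stop, status, X = NULL) {
  check_rows(t_start, t_stop, status, X, par)
  lam <- exp(par[1]); gam <- exp(par[2])
  eta <- if (is.null(X)) 0 else drop(X %*% par[-(1:2)])
  d <- status
  sum(d * (par[1] + par[2] + (gam - 1) * log(t_stop) + eta)) -
    sum(lam * exp(eta) * (t_stop^gam - pow0(t_start, gam)))
}

# analytic score of weibull_ph_loglik in (log lambda, log gamma, beta)
weibull_ph_score <- function(par, t_start, t_stop, status, X = NULL) {
  lam <- exp(par[1]); gam <- exp(par[2])
  eta <- if (is.null(X)) 0 else drop(X %*% par[-(1:2)])
  H1 <- lam * exp(eta) * t_stop^gam
  H0 <- lam * exp(eta) * pow0(t_start, gam)
  dH <- H1 - H0
  g1 <- sum(status - dH)
  lt1 <- log(t_stop)
  lt0 <- ifelse(t_start > 0, log(t_start), 0)
  g2 <- sum(status * (1 + gam * lt1)) - gam * sum(H1 * lt1 - H0 * lt0)
  g <- c(g1, g2)
  if (!is.null(X)) g <- c(g, drop(crossprod(X, status - dH)))
  g
}

pow0 <- function(t, gam) ifelse(t > 0, t^gam, 0)

check_rows <- function(t_start, t_stop, status, X, par) {
  if (any(!is.finite(par))) stop("non-finite parameters")
  if (any(t_start < 0) || any(t_stop <= t_start))
    stop("at-risk intervals require 0 <= t_start < t_stop")
  if (!all(status %in% 0:1)) stop("status must be 0/1")
  if (!is.null(X) && length(par) != 2L + ncol(X))
    stop("parameter length does not match design matrix")
  invisible(TRUE)
}

#' Fit a Weibull PH model to one transition
#'
#' Maximum likelihood on the stacked long-format rows of a single
#' transition, honouring delayed entry. Starting values come from the
#' exponential special case (shape 1, rate = events/exposure, beta = 0);
#' on failure up to five restarts jitter the log shape (deterministic
#' jitter stream). The covariance is the inverse observed information from
#' a numerical Hessian at the optimum.
#'
#' @param long An `msm_long` data.frame (or any data.frame with columns
#'   `transition`, `t_start`, `t_stop`, `status` plus covariates).
#' @param transition Integer transition index to fit.
#' @param covariates Character vector of covariate column names (binary
#'   covariates coded 0/1; continuous accepted).
#' @param fixed_shape Optional positive value to hold the Weibull shape
#'   fixed (1 gives the exponential model).
#' @return Object of class `weibull_ph`: `transition`, `shape`, `rate`,
#'   `coef` (log hazard ratios), `par` (full `(log lambda, log gamma,
#'   beta)` vector), `vcov` (over the full vector; NULL with
#'   `vcov_ok = FALSE` if the Hessian is singular), `loglik`, `n_events`,
#'   `n_rows`, `npar` (free parameters), `covariates`.
#' @export
fit_transition <- function(long, transition, covariates = character(),
                           fixed_shape = NULL) {
  rows <- long[long$transition == transition, , drop = FALSE]
  rows <- rows[stats::complete.cases(rows[, c("t_start", "t_stop", "status",
                                              covariates), drop = FALSE]), ,
               drop = FALSE]
  if (!nrow(rows)) stop("no rows for transition ", transition)
  if (sum(rows$status) == 0)
    stop("transition ", transition, " has zero events; drop it or its ",
         "covariates")
  X <- if (length(covariates))
    as.matrix(rows[, covariates, drop = FALSE]) else NULL
  if (!is.null(X) && qr(cbind(1, X))$rank < ncol(X) + 1)
    stop("design matrix for transition ", transition, " is rank deficient")
  exposure <- sum(rows$t_stop - rows$t_start)
  start <- c(log(sum(rows$status) / exposure), 0, rep(0, length(covariates)))
  free <- rep(TRUE, length(start))
  if (!is.null(fixed_shape)) {
    start[2] <- log(fixed_shape)
    free[2] <- FALSE
  }
  fn <- function(p_free) {
    p <- start; p[free] <- p_free
    -weibull_ph_loglik(p, rows$t_start, rows$t_stop, rows$status, X)
  }
  gr <- function(p_free) {
    p <- start; p[free] <- p_free
    -weibull_ph_score(p, rows$t_start, rows$t_stop, rows$status, X)[free]
  }
  scale0 <- max(1, abs(fn(start[free])))
  best <- NULL
  jitter_rng <- local({  # deterministic restart jitters, isolated from .GRS
    state <- 1234L + 7L * as.integer(transition)
    function() {
      state <<- (1103515245 * state + 12345) %% 2147483648
      (state / 2147483648 - 0.5)
    }
  })
  for (attempt in 0:5) {
    st <- start[free]
    if (attempt > 0 && is.null(fixed_shape) && free[2])
      st[2] <- st[2] + attempt * 0.4 * jitter_rng()
    opt <- try(stats::optim(st, fn, gr, method = "BFGS",
                            control = list(maxit = 1000, reltol = 1e-12)),
               silent = TRUE)
    if (inherits(opt, "try-error")) next
    g <- gr(opt$par)
    ok <- max(abs(g)) / scale0 < 1e-5
    if (is.null(best) || opt$value < best$value) best <- c(opt, list(ok = ok))
    if (ok && opt$convergence == 0) break
  }
  if (is.null(best))
    stop("optimization failed for transition ", transition,
         " after restarts")
  if (!best$ok && best$convergence != 0)
    stop("no convergence for transition ", transition,
         "; final gradient norm ", signif(max(abs(gr(best$par))), 3))
  par <- start; par[free] <- best$par
  H <- try(stats::optimHess(best$par, fn, gr), silent = TRUE)
  vcov_free <- if (!inherits(H, "try-error"))
    try(solve(H), silent = TRUE) else H
  vcov <- NULL; vcov_ok <- FALSE
  if (!inherits(vcov_free, "try-error") &&
      all(is.finite(vcov_free)) && all(diag(vcov_free) > 0)) {
    vcov <- matrix(0, length(par), length(par))
    vcov[free, free] <- (vcov_free + t(vcov_free)) / 2
    vcov_ok <- TRUE
  }
  pn <- c("log_lambda", "log_gamma", covariates)
  if (!is.null(vcov)) dimnames(vcov) <- list(pn, pn)
  structure(list(transition = transition,
                 shape = exp(par[2]), rate = exp(par[1]),
                 coef = stats::setNames(par[-(1:2)], covariates),
                 par = stats::setNames(par, pn),
                 vcov = vcov, vcov_ok = vcov_ok,
                 loglik = -best$value,
                 n_events = sum(rows$status), n_rows = nrow(rows),
                 npar = sum(free), covariates = covariates,
                 fixed_shape = fixed_shape),
            class = "weibull_ph")
}

#' @export
logLik.weibull_ph <- function(object, ...) {
  structure(object$loglik, df = object$npar, class = "logLik")
}

#' @export
print.weibull_ph <- function(x, ...) {
  cat(sprintf(
    "Weibull PH fit, transition %d: shape %.4g, rate %.4g, logLik %.3f, AIC %.2f\n",
    x$transition, x$shape, x$rate, x$loglik, stats::AIC(x)))
  if (length(x$coef)) print(hazard_ratios(x))
  invisible(x)
}

#' Hazard ratios with Wald confidence intervals
#'
#' @param fit A `weibull_ph` fit with an available covariance.
#' @param level Confidence level (default 0.95).
#' @return data.frame with `covariate`, `HR`, `lower`, `upper`, `p`
#'   (two-sided Wald test of beta = 0).
#' @export
hazard_ratios <- function(fit, level = 0.95) {
  if (!fit$vcov_ok) stop("covariance unavailable for this fit")
  if (!length(fit$coef)) return(data.frame(covariate = character(),
                                           HR = numeric(), lower = numeric(),
                                           upper = numeric(), p = numeric()))
  se <- sqrt(diag(fit$vcov)[-(1:2)])
  z <- stats::qnorm(1 - (1 - level) / 2)
  data.frame(covariate = names(fit$coef),
             HR = exp(fit$coef),
             lower = exp(fit$coef - z * se),
             upper = exp(fit$coef + z * se),
             p = 2 * stats::pnorm(-abs(fit$coef / se)),
             row.names = NULL)
}

#' Fit every transition of a multistate model
#'
#' @param long An `msm_long` data.frame.
#' @param space A `state_space`.
#' @param covariates Either one character vector applied to every
#'   transition, or a list indexed by transition (missing entries mean
#'   baseline-only).
#' @param fixed_shape Optional shape passed through to [fit_transition()].
#' @return Object of class `msm_fit`: `space` plus `fits`, one
#'   `weibull_ph` per transition.
#' @export
fit_multistate <- function(long, space, covariates = character(),
                           fixed_shape = NULL) {
  K <- nrow(space$transitions)
  covs <- if (is.list(covariates)) covariates else
    rep(list(covariates), K)
  fits <- lapply(seq_len(K), function(k) {
    ck <- if (k <= length(covs) && !is.null(covs[[k]])) covs[[k]]
          else character()
    fit_transition(long, k, ck, fixed_shape = fixed_shape)
  })
  msm_fit(space, fits)
}

#' Bundle per-transition fits into a predictive model
#'
#' @param space A `state_space`.
#' @param fits List with one `weibull_ph` (or bare
#'   `list(shape, rate, beta)`) per transition, in transition order.
#' @return Object of class `msm_fit`.
#' @export
msm_fit <- function(space, fits) {
  if (length(fits) != nrow(space$transitions))
    stop("need exactly one fit per transition")
  structure(list(space = space, fits = fits), class = "msm_fit")
}

#' @export
print.msm_fit <- function(x, ...) {
  cat("Multistate Weibull PH model,", length(x$fits), "transitions\n")
  for (f in x$fits)
    if (inherits(f, "weibull_ph")) print(f) else
      cat(sprintf("  transition: shape %.4g rate %.4g (fixed parameters)\n",
                  f$shape, f$rate))
  invisible(x)
}

# normalize a fit or parameter list to (shape, rate, beta named vector)
trans_par <- function(f) {
  beta <- if (inherits(f, "weibull_ph")) f$coef else f$beta
  if (is.null(beta)) beta <- stats::setNames(numeric(0), character(0))
  list(shape = f$shape, rate = f$rate, beta = beta)
}

#' Serialize fits to JSON and a tabular CSV (transition, covariate, HR, CI, p)
#'
#' @param fits List of `weibull_ph` fits.
#' @param json_path,csv_path Output paths (NULL to skip either).
#' @return Invisibly, the hazard-ratio table (all transitions stacked).
#' @export
write_fit_results <- function(fits, json_path = NULL, csv_path = NULL) {
  tabs <- lapply(fits, function(f) {
    if (!length(f$coef) || !f$vcov_ok) return(NULL)
    cbind(transition = f$transition, hazard_ratios(f))
  })
  tab <- do.call(rbind, tabs)
  if (!is.null(json_path)) {
    jsonlite::write_json(lapply(fits, function(f)
      list(transition = f$transition, shape = f$shape, rate = f$rate,
           coef = as.list(f$coef),
           vcov = if (f$vcov_ok) f$vcov else NULL,
           loglik = f$loglik, aic = stats::AIC(f),
           n_events = f$n_events, n_rows = f$n_rows)),
      json_path, auto_unbox = TRUE, digits = NA, null = "null")
  }
  if (!is.null(csv_path) && !is.null(tab))
    utils::write.csv(tab, csv_path, row.names = FALSE)
  invisible(tab)
}
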