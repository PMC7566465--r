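# Event-history simulation. Next-event times invert the total cumulative
# hazard out of the current state: with E ~ Exp(1), solve
#   sum_k [H_k(t) - H_k(s)] = E
# for t by bisection (60 halvings of [s, horizon], well below 1e-8 years),
# then draw the destination with probability proportional to the
# cause-specific hazards h_k(t) at the event time. The same sampler drives
# both cohort generation and Monte Carlo prediction.

# Vectorized over paths. cmat: n x K matrix of per-path multipliers
# rate_k * exp(x'beta_k); t0, horizon: vectors of entry and censoring
# times. An event falling exactly on the horizon counts as a transition
# (transition wins over censoring). Returns Inf-padded entry-time and
# state matrices (column 1 = the start), plus each path's final state.
sim_paths <- function(space, shapes, cmat, start_state, t0, horizon) {
  n <- nrow(cmat)
  tr <- space$transitions
  cur_state <- rep_len(start_state, n)
  cur_time <- rep_len(t0, n)
  horizon <- rep_len(horizon, n)
  states_m <- matrix(cur_state, n, 1)
  times_m <- matrix(cur_time, n, 1)
  active <- !space$absorbing[match(cur_state, space$states)] &
    cur_time < horizon
  while (any(active)) {
    new_state <- rep(NA_integer_, n)
    new_time <- rep(Inf, n)
    for (s in unique(cur_state[active])) {
      ks <- transitions_from(space, s)
      idx <- which(active & cur_state == s)
      cs <- cmat[idx, ks, drop = FALSE]
      gs <- shapes[ks]
      te <- cur_time[idx]
      hz <- horizon[idx]
      cumhaz <- function(t) {       # total cumulative hazard from te to t
        acc <- 0
        for (j in seq_along(ks))
          acc <- acc + cs[, j] * (t^gs[j] - pow0(te, gs[j]))
        acc
      }
      E <- stats::rexp(length(idx))
      ev <- cumhaz(hz) >= E
      if (any(ev)) {
        lo <- te[ev]; hi <- hz[ev]
        csE <- cs[ev, , drop = FALSE]; teE <- te[ev]; Ee <- E[ev]
        for (it in 1:60) {
          mid <- (lo + hi) / 2
          acc <- 0
          for (j in seq_along(ks))
            acc <- acc + csE[, j] * (mid^gs[j] - pow0(teE, gs[j]))
          below <- acc < Ee
          lo[below] <- mid[below]
          hi[!below] <- mid[!below]
        }
        tev <- (lo + hi) / 2
        W <- matrix(0, sum(ev), length(ks))
        for (j in seq_along(ks))
          W[, j] <- csE[, j] * gs[j] * tev^(gs[j] - 1)
        cum <- W
        if (ncol(W) > 1)
          for (j in 2:ncol(W)) cum[, j] <- cum[, j - 1] + W[, j]
        u <- stats::runif(sum(ev)) * cum[, ncol(W)]
        kpick <- rowSums(cum < u) + 1L
        ii <- idx[ev]
        new_state[ii] <- tr$to[ks][kpick]
        new_time[ii] <- tev
      }
      active[idx[!ev]] <- FALSE     # censored at horizon in state s
    }
    moved <- !is.na(new_state)
    if (!any(moved)) break
    cur_state[moved] <- new_state[moved]
    cur_time[moved] <- new_time[moved]
    states_m <- cbind(states_m, ifelse(moved, new_state, NA_integer_))
    times_m <- cbind(times_m, ifelse(moved, new_time, Inf))
    active[moved] <- !space$absorbing[match(cur_state[moved],
                                            space$states)] &
      cur_time[moved] < horizon[moved]
  }
  list(states = states_m, times = times_m,
       final_state = cur_state, final_time = cur_time)
}

# state occupied by each path at each grid time (n x length(times))
states_at <- function(paths, times, space) {
  n <- nrow(paths$times)
  out <- matrix(NA_integer_, n, length(times))
  for (i in seq_along(times)) {
    j <- rowSums(paths$times <= times[i])
    out[, i] <- paths$states[cbind(seq_len(n), j)]
  }
  out
}

#' Specify a synthetic cohort
#'
#' @param n_subjects Cohort size.
#' @param space A `state_space`.
#' @param shapes,rates Per-transition Weibull shape and rate-scale vectors
#'   (baseline hazard `rate * shape * t^(shape - 1)`).
#' @param covariates Named list; each element is
#'   `list(prevalence =, loghr =)` with `loghr` a length-K vector of
#'   per-transition log hazard ratios. Covariates are drawn independently
#'   as Bernoulli(prevalence).
#' @param admin_horizon Administrative censoring time (years).
#' @param dropout_rate Rate of independent exponential dropout (0 = none).
#' @param seed Default RNG seed for [generate_cohort()].
#' @return Object of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects, space, shapes, rates,
                          covariates = list(), admin_horizon = Inf,
                          dropout_rate = 0, seed = 1) {
  K <- nrow(space$transitions)
  stopifnot(n_subjects >= 1, length(shapes) == K, length(rates) == K,
            all(shapes > 0), all(rates > 0), dropout_rate >= 0)
  for (nm in names(covariates)) {
    cv <- covariates[[nm]]
    if (cv$prevalence < 0 || cv$prevalence > 1)
      stop("prevalence of ", nm, " outside [0, 1]")
    if (length(cv$loghr) != K)
      stop("covariate ", nm, " needs one log-HR per transition")
  }
  structure(list(n_subjects = as.integer(n_subjects), space = space,
                 shapes = shapes, rates = rates, covariates = covariates,
                 admin_horizon = admin_horizon,
                 dropout_rate = dropout_rate, seed = as.integer(seed)),
            class = "cohort_config")
}

#' Generate a synthetic cohort
#'
#' Draws covariates by prevalence, simulates each subject's path from the
#' initial state at time 0 with the shared total-hazard-inversion sampler,
#' and censors at the minimum of the administrative horizon and an
#' exponential dropout time. A transition landing exactly on the censoring
#' time wins over censoring. Reproducible: identical seed and config give
#' an identical cohort.
#'
#' @param config A `cohort_config`.
#' @param seed RNG seed (defaults to the config's).
#' @return Wide subject data.frame (see [read_subjects()]).
#' @export
generate_cohort <- function(config, seed = config$seed) {
  space <- config$space
  n <- config$n_subjects
  K <- nrow(space$transitions)
  withr_seed(seed, {
    cn <- names(config$covariates)
    X <- matrix(0L, n, length(cn), dimnames = list(NULL, cn))
    for (nm in cn)
      X[, nm] <- stats::rbinom(n, 1, config$covariates[[nm]]$prevalence)
    eta <- matrix(0, n, K)
    for (nm in cn)
      eta <- eta + outer(X[, nm], config$covariates[[nm]]$loghr)
    cmat <- sweep(exp(eta), 2, config$rates, `*`)
    dropout <- if (config$dropout_rate > 0)
      stats::rexp(n, config$dropout_rate) else rep(Inf, n)
    horizon <- pmin(config$admin_horizon, dropout)
    paths <- sim_paths(space, config$shapes, cmat,
                       start_state = first_nonabsorbing(space),
                       t0 = rep(0, n), horizon = horizon)
  })
  out <- data.frame(subject_id = sprintf("S%06d", seq_len(n)))
  out <- cbind(out, as.data.frame(X))
  for (s in setdiff(space$states, first_nonabsorbing(space))) {
    cl <- state_time_col(space$labels[match(s, space$states)])
    tcol <- rep(NA_real_, n)
    if (ncol(paths$states) > 1)
      for (j in 2:ncol(paths$states)) {
        sel <- !is.na(paths$states[, j]) & paths$states[, j] == s
        tcol[sel] <- paths$times[sel, j]
      }
    out[[cl]] <- tcol
  }
  absorbed <- space$absorbing[match(paths$final_state, space$states)]
  out$time_censor <- ifelse(absorbed, NA_real_, horizon)
  out
}

#' Read or write a cohort configuration as YAML
#' @param config A `cohort_config`.
#' @param path File path.
#' @export
write_cohort_config <- function(config, path) {
  y <- list(n_subjects = config$n_subjects,
            shapes = config$shapes, rates = config$rates,
            covariates = lapply(config$covariates, function(cv)
              list(prevalence = cv$prevalence, loghr = cv$loghr)),
            admin_horizon = config$admin_horizon,
            dropout_rate = config$dropout_rate, seed = config$seed,
            space = list(
              states = lapply(seq_along(config$space$states), function(i)
                list(id = config$space$states[i],
                     label = config$space$labels[i],
                     absorbing = config$space$absorbing[i])),
              transitions = lapply(seq_len(nrow(config$space$transitions)),
                                   function(k)
                c(config$space$transitions$from[k],
                  config$space$transitions$to[k]))))
  yaml::write_yaml(y, path, precision = 15)
  invisible(path)
}

#' @rdname write_cohort_config
#' @export
read_cohort_config <- function(path) {
  y <- yaml::read_yaml(path)
  space <- state_space(
    states = vapply(y$space$states, `[[`, 0, "id"),
    labels = vapply(y$space$states, `[[`, "", "label"),
    absorbing = vapply(y$space$states, `[[`, TRUE, "absorbing"),
    transitions = do.call(rbind, lapply(y$space$transitions, unlist)))
  cohort_config(n_subjects = y$n_subjects, space = space,
                shapes = unlist(y$shapes), rates = unlist(y$rates),
                covariates = lapply(y$covariates, function(cv)
                  list(prevalence = cv$prevalence,
                       loghr = unlist(cv$loghr))),
                admin_horizon = y$admin_horizon,
                dropout_rate = y$dropout_rate, seed = y$seed)
}
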