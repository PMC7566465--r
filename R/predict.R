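# Transition-probability machinery for a fitted Markov multistate model.
# P_ab(s,t) solves the Kolmogorov forward equation dP/dt = P Q(t) with
# P(s,s) = I, where Q(t) collects the fitted transition hazards.

# per-transition multiplier c_k = rate_k * exp(x'beta_k) for a profile x
profile_consts <- function(model, x) {
  vapply(model$fits, function(f) {
    p <- trans_par(f)
    eta <- if (length(p$beta)) {
      miss <- setdiff(names(p$beta), names(x))
      if (length(miss)) stop("profile lacks covariate ", miss[1])
      sum(p$beta * x[names(p$beta)])
    } else 0
    p$rate * exp(eta)
  }, 0)
}

model_shapes <- function(model)
  vapply(model$fits, function(f) trans_par(f)$shape, 0)

#' Transition intensity matrix of a fitted model
#'
#' Q_ab(t) is the hazard of the a -> b transition at time t for covariate
#' profile `x`; the diagonal is minus the row sum, and absorbing rows are
#' zero.
#'
#' @param model An `msm_fit`.
#' @param t Time (years, > 0).
#' @param x Named covariate profile (values for every fitted covariate).
#' @return Square matrix over the model's states.
#' @export
intensity_matrix <- function(model, t, x = NULL) {
  shapes <- model_shapes(model)
  if (any(t < 0) || (any(t == 0) && any(shapes < 1)))
    stop("intensity undefined at t <= 0 when any shape < 1")
  cc <- profile_consts(model, x)
  intensity_matrix_(model$space, shapes, cc, t)
}

intensity_matrix_ <- function(space, shapes, cc, t) {
  ns <- length(space$states)
  Q <- matrix(0, ns, ns, dimnames = list(space$labels, space$labels))
  tr <- space$transitions
  h <- cc * shapes * t^(shapes - 1)
  for (k in seq_len(nrow(tr))) {
    a <- match(tr$from[k], space$states); b <- match(tr$to[k], space$states)
    Q[a, b] <- h[k]
  }
  diag(Q) <- -rowSums(Q)
  Q
}

#' Transition probabilities P(s, t)
#'
#' Deterministic prediction by adaptive integration of the Kolmogorov
#' forward equation (`method = "ode"`), or Monte Carlo prediction by
#' simulating Markov paths whose next-event times invert the total
#' cumulative hazard (`method = "sim"`).
#'
#' @param model An `msm_fit`.
#' @param s Conditioning time (years, >= 0).
#' @param times Increasing prediction grid, all > s.
#' @param x Named covariate profile.
#' @param method `"ode"` (default) or `"sim"`.
#' @param n_paths Paths per starting state for `method = "sim"`.
#' @param seed RNG seed for `method = "sim"`.
#' @param neg_tol Largest negative ODE excursion clipped to zero before row
#'   renormalization; anything more negative is an error.
#' @return Object of class `prob_curves`: `times`, array `P` (time x from
#'   x to), `s`, `profile`, `method`.
#' @export
transition_probabilities <- function(model, s = 0, times, x = NULL,
                                     method = c("ode", "sim"),
                                     n_paths = 10000, seed = 1,
                                     neg_tol = 1e-9) {
  method <- match.arg(method)
  if (s < 0 || any(times <= s)) stop("need s >= 0 and times > s")
  if (is.unsorted(times, strictly = TRUE)) stop("times must increase")
  if (method == "ode")
    tp_ode(model, s, times, x, neg_tol)
  else
    tp_sim(model, s, times, x, n_paths, seed)
}

tp_ode <- function(model, s, times, x, neg_tol) {
  space <- model$space
  ns <- length(space$states)
  shapes <- model_shapes(model)
  cc <- profile_consts(model, x)
  s0 <- if (s == 0 && any(shapes < 1)) 1e-6 else s  # hazard singular at 0
  rhs <- function(t, y, parms) {
    P <- matrix(y, ns, ns)
    list(as.vector(P %*% intensity_matrix_(space, shapes, cc, t)))
  }
  sol <- deSolve::ode(y = as.vector(diag(ns)), times = c(s0, times),
                      func = rhs, parms = NULL, method = "lsoda",
                      rtol = 1e-10, atol = 1e-12)
  if (attr(sol, "istate")[1] < 0) stop("ODE solver failed: ",
                                       paste(attr(sol, "istate"), collapse = " "))
  P <- array(sol[-1, -1, drop = FALSE], dim = c(length(times), ns, ns),
             dimnames = list(NULL, space$labels, space$labels))
  if (any(P < -neg_tol))
    stop("negative transition probability beyond tolerance: ", min(P))
  P[P < 0] <- 0
  for (i in seq_len(dim(P)[1])) P[i, , ] <- P[i, , ] / rowSums(P[i, , ])
  structure(list(times = times, P = P, s = s, profile = x, method = "ode",
                 space = space), class = "prob_curves")
}

tp_sim <- function(model, s, times, x, n_paths, seed) {
  space <- model$space
  ns <- length(space$states)
  shapes <- model_shapes(model)
  cc <- profile_consts(model, x)
  horizon <- max(times)
  P <- array(0, dim = c(length(times), ns, ns),
             dimnames = list(NULL, space$labels, space$labels))
  withr_seed(seed, {
    for (a in seq_len(ns)) {
      if (space$absorbing[a]) { P[, a, a] <- 1; next }
      cmat <- matrix(cc, n_paths, length(cc), byrow = TRUE)
      paths <- sim_paths(space, shapes, cmat,
                         start_state = space$states[a],
                         t0 = rep(max(s, 0), n_paths),
                         horizon = rep(horizon, n_paths))
      st <- states_at(paths, times, space)
      for (b in seq_len(ns))
        P[, a, b] <- colMeans(st == space$states[b])
    }
  })
  structure(list(times = times, P = P, s = s, profile = x, method = "sim",
                 n_paths = n_paths, space = space), class = "prob_curves")
}

# run code with a temporary RNG seed, restoring the caller's RNG state
withr_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  eval.parent(substitute(code))
}

#' State occupation probabilities from diagnosis
#'
#' The occupation vector at time t is the initial-state row of P(0, t).
#' With `newdata`, curves are averaged over the cohort's covariate rows
#' (population-averaged prediction); with `x`, a single reference profile
#' is used.
#'
#' @inheritParams transition_probabilities
#' @param newdata Optional data.frame of covariate rows to average over.
#' @param initial_state Starting (non-absorbing) state code.
#' @return Object of class `occupation_curves`: `times`, matrix
#'   `occupation` (time x state), stacked cumulative `bands`, `method`.
#' @export
state_occupation <- function(model, times, x = NULL, newdata = NULL,
                             initial_state = first_nonabsorbing(model$space),
                             method = c("ode", "sim"), n_paths = 10000,
                             seed = 1) {
  method <- match.arg(method)
  space <- model$space
  if (space$absorbing[match(initial_state, space$states)])
    stop("initial state must be non-absorbing")
  a <- match(initial_state, space$states)
  covs <- unique(unlist(lapply(model$fits,
                               function(f) names(trans_par(f)$beta))))
  occ_for <- function(xi) {
    pc <- transition_probabilities(model, 0, times, xi, method = method,
                                   n_paths = n_paths, seed = seed)
    pc$P[, a, , drop = TRUE]
  }
  if (!is.null(newdata) && length(covs)) {
    prof <- unique(newdata[, covs, drop = FALSE])
    w <- as.numeric(table(do.call(paste, newdata[, covs, drop = FALSE]))[
      do.call(paste, prof)])
    w <- w / sum(w)
    occ <- 0
    for (j in seq_len(nrow(prof)))
      occ <- occ + w[j] * occ_for(unlist(prof[j, , drop = TRUE]))
  } else {
    occ <- occ_for(x)
  }
  occ <- matrix(occ, nrow = length(times),
                dimnames = list(NULL, space$labels))
  bands <- t(apply(occ, 1, cumsum))
  structure(list(times = times, occupation = occ, bands = bands,
                 initial_state = initial_state, method = method,
                 space = space), class = "occupation_curves")
}

#' Tidy CSV export of probability curves
#'
#' @param pc A `prob_curves` object.
#' @param path Output path.
#' @return The tidy data.frame, invisibly.
#' @export
write_curves <- function(pc, path = NULL) {
  ns <- length(pc$space$states)
  g <- expand.grid(i = seq_along(pc$times), a = seq_len(ns), b = seq_len(ns))
  out <- data.frame(time = pc$times[g$i],
                    from_state = pc$space$labels[g$a],
                    to_state = pc$space$labels[g$b],
                    probability = pc$P[cbind(g$i, g$a, g$b)],
                    method = pc$method)
  if (!is.null(path)) utils::write.csv(out, path, row.names = FALSE)
  invisible(out)
}

#' @rdname write_curves
#' @param oc An `occupation_curves` object.
#' @export
write_occupation <- function(oc, path = NULL) {
  g <- expand.grid(i = seq_along(oc$times), s = seq_len(ncol(oc$occupation)))
  out <- data.frame(time = oc$times[g$i],
                    state = oc$space$labels[g$s],
                    probability = oc$occupation[cbind(g$i, g$s)],
                    method = oc$method)
  if (!is.null(path)) utils::write.csv(out, path, row.names = FALSE)
  invisible(out)
}

#' Default prediction grid
#'
#' 401 points spanning 0 to 25 years; the first point is shifted to 1e-6
#' to avoid the Weibull hazard singularity when a shape is below 1.
#' @param horizon Last time (years).
#' @param n Number of points.
#' @export
default_grid <- function(horizon = 25, n = 401) {
  g <- seq(0, horizon, length.out = n)
  g[1] <- 1e-6
  g
}
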