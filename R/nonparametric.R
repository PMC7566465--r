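# Nonparametric estimators on the stacked long format, used as model-free
# oracles for the parametric predictions. Risk sets honour delayed entry:
# a row (t_start, t_stop] is at risk at t iff t_start < t <= t_stop, so a
# subject censored at t still counts in the risk set of an event at t
# (censor-after-event tie convention).

# number at risk at each time in `at`: #(t_start < t) - #(t_stop < t)
risk_at <- function(t_start, t_stop, at) {
  findInterval(at, sort(t_start), left.open = TRUE) -
    findInterval(at, sort(t_stop), left.open = TRUE)
}

# events per transition at each time in `at` (K x length(at) matrix)
events_at <- function(long, K, at) {
  out <- matrix(0L, K, length(at))
  ev <- long[long$status == 1, c("transition", "t_stop")]
  key <- match(ev$t_stop, at)
  keep <- !is.na(key)
  for (r in which(keep))
    out[ev$transition[r], key[r]] <- out[ev$transition[r], key[r]] + 1L
  out
}

#' Nelson-Aalen cumulative transition hazard
#'
#' At each event time t the cumulative hazard jumps by
#' (events at t) / (number at risk just before t), risk sets honouring
#' delayed entry.
#'
#' @param long An `msm_long` data.frame.
#' @param transition Transition index.
#' @return Object of class `step_curve`: `jump_times`, `increments`,
#'   `values` (the cumulative hazard after each jump). No events gives a
#'   flat zero curve.
#' @export
nelson_aalen <- function(long, transition) {
  rows <- long[long$transition == transition, , drop = FALSE]
  ev <- sort(unique(rows$t_stop[rows$status == 1]))
  d <- vapply(ev, function(t) sum(rows$status == 1 & rows$t_stop == t), 0)
  y <- risk_at(rows$t_start, rows$t_stop, ev)
  inc <- if (length(ev)) d / y else numeric(0)
  structure(list(jump_times = ev, increments = inc, values = cumsum(inc),
                 transition = transition),
            class = "step_curve")
}

#' Evaluate a step curve
#' @param curve A `step_curve`.
#' @param times Evaluation times.
#' @export
step_curve_at <- function(curve, times) {
  vapply(times, function(t) {
    j <- sum(curve$jump_times <= t)
    if (j == 0) 0 else curve$values[j]
  }, 0)
}

#' Aalen-Johansen transition probabilities
#'
#' Product-integral over the observed event times of (I + dA(t)), where
#' dA(t) collects the Nelson-Aalen increments of every transition into an
#' intensity-increment matrix. Rows of the estimate sum to one exactly
#' (product of stochastic matrices). In a two-state model this reduces to
#' one minus Kaplan-Meier.
#'
#' @param long An `msm_long` data.frame.
#' @param space A `state_space`.
#' @param s Conditioning time; event times at or before `s` are ignored.
#' @param times Output grid (all > s).
#' @return A `prob_curves` object with `method = "aalen-johansen"`.
#' @export
aalen_johansen <- function(long, space, s = 0, times) {
  ns <- length(space$states)
  tr <- space$transitions
  K <- nrow(tr)
  ev_times <- sort(unique(long$t_stop[long$status == 1 & long$t_stop > s]))
  D <- events_at(long, K, ev_times)
  # one representative transition per from-state avoids double-counting
  # the risk set across a state's stacked rows
  Y <- matrix(0, ns, length(ev_times))
  for (a in unique(tr$from)) {
    k <- min(tr$transition[tr$from == a])
    rows <- long[long$transition == k, , drop = FALSE]
    Y[match(a, space$states), ] <- risk_at(rows$t_start, rows$t_stop,
                                           ev_times)
  }
  P <- diag(ns)
  out <- array(0, dim = c(length(times), ns, ns),
               dimnames = list(NULL, space$labels, space$labels))
  gi <- 1L
  for (e in seq_along(ev_times)) {
    while (gi <= length(times) && times[gi] < ev_times[e]) {
      out[gi, , ] <- P
      gi <- gi + 1L
    }
    dA <- matrix(0, ns, ns)
    for (k in which(D[, e] > 0)) {
      a <- match(tr$from[k], space$states)
      b <- match(tr$to[k], space$states)
      dA[a, b] <- dA[a, b] + D[k, e] / Y[a, e]
    }
    diag(dA) <- -rowSums(dA)
    if (any(1 + diag(dA) < 0))
      stop("Aalen-Johansen step at t = ", ev_times[e],
           " gives a negative diagonal; data too sparse")
    P <- P %*% (diag(ns) + dA)
  }
  while (gi <= length(times)) {
    out[gi, , ] <- P
    gi <- gi + 1L
  }
  structure(list(times = times, P = out, s = s, profile = NULL,
                 method = "aalen-johansen", space = space),
            class = "prob_curves")
}
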