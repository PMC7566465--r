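#' Define a multistate topology
#'
#' A state space is a directed graph of integer-coded states with a set of
#' allowed transitions. Transitions are indexed 1..K in the order given;
#' absorbing states admit no outgoing transition.
#'
#' @param states Integer vector of state codes (order defines matrix order).
#' @param labels Character vector of state labels, same length as `states`.
#' @param absorbing Logical vector flagging absorbing states.
#' @param transitions Two-column matrix or data.frame of (from, to) state
#'   codes; row order defines the 1-based transition index.
#' @return An object of class `state_space` with elements `states`,
#'   `labels`, `absorbing`, `transitions` (data.frame with columns
#'   `transition`, `from`, `to`).
#' @examples
#' ss <- state_space(1:2, c("alive", "dead"), c(FALSE, TRUE),
#'                   cbind(1, 2))
#' validate_state_space(ss)
#' @export
state_space <- function(states, labels, absorbing, transitions) {
  states <- as.integer(states)
  transitions <- as.data.frame(transitions)
  if (ncol(transitions) == 2L) names(transitions) <- c("from", "to")
  tr <- data.frame(transition = seq_len(nrow(transitions)),
                   from = as.integer(transitions$from),
                   to = as.integer(transitions$to))
  obj <- structure(list(states = states,
                        labels = as.character(labels),
                        absorbing = as.logical(absorbing),
                        transitions = tr),
                   class = "state_space")
  validate_state_space(obj)
}

#' The four-state pre-PMF disease model
#'
#' States: 1 = pre-PMF (initial), 2 = overt PMF, 3 = AML, 4 = death
#' (absorbing). Six transitions: 1->2, 1->3, 1->4, 2->3, 2->4, 3->4.
#'
#' @return A `state_space`.
#' @export
pmf_state_space <- function() {
  state_space(states = 1:4,
              labels = c("pre-PMF", "overt PMF", "AML", "death"),
              absorbing = c(FALSE, FALSE, FALSE, TRUE),
              transitions = rbind(c(1, 2), c(1, 3), c(1, 4),
                                  c(2, 3), c(2, 4), c(3, 4)))
}

#' Validate a state space
#'
#' Checks the structural invariants: consistent lengths, unique states,
#' transitions between known states, no transition out of an absorbing
#' state, no duplicated (from, to) pair, and 1..K transition indices.
#'
#' @param space A `state_space`.
#' @return The space, unchanged, if valid; otherwise an error naming the
#'   offending transition.
#' @export
validate_state_space <- function(space) {
  stopifnot(inherits(space, "state_space"))
  n <- length(space$states)
  if (length(space$labels) != n || length(space$absorbing) != n)
    stop("states, labels and absorbing must have equal length")
  if (anyDuplicated(space$states))
    stop("duplicate state codes")
  tr <- space$transitions
  if (!identical(tr$transition, seq_len(nrow(tr))))
    stop("transition indices must be 1..K in order")
  bad <- !(tr$from %in% space$states) | !(tr$to %in% space$states)
  if (any(bad))
    stop("transition ", tr$transition[which(bad)[1]],
         " references an unknown state")
  self <- tr$from == tr$to
  if (any(self))
    stop("transition ", tr$transition[which(self)[1]], " is a self-loop")
  dup <- duplicated(tr[c("from", "to")])
  if (any(dup))
    stop("duplicate transition (", tr$from[which(dup)[1]], " -> ",
         tr$to[which(dup)[1]], ")")
  abs_states <- space$states[space$absorbing]
  out_abs <- tr$from %in% abs_states
  if (any(out_abs))
    stop("transition ", tr$transition[which(out_abs)[1]],
         " leaves absorbing state ", tr$from[which(out_abs)[1]])
  space
}

#' @export
print.state_space <- function(x, ...) {
  cat("Multistate topology:", length(x$states), "states,",
      nrow(x$transitions), "transitions\n")
  for (i in seq_along(x$states))
    cat(sprintf("  %d: %s%s\n", x$states[i], x$labels[i],
                if (x$absorbing[i]) " (absorbing)" else ""))
  for (k in seq_len(nrow(x$transitions)))
    cat(sprintf("  trans %d: %s -> %s\n", k,
                x$labels[match(x$transitions$from[k], x$states)],
                x$labels[match(x$transitions$to[k], x$states)]))
  invisible(x)
}

# transitions emanating from state `from` (integer transition indices)
transitions_from <- function(space, from) {
  space$transitions$transition[space$transitions$from == from]
}

first_nonabsorbing <- function(space) {
  space$states[!space$absorbing][1]
}

#' Read / write a state space as YAML
#'
#' The YAML schema has a `states` list (id, label, absorbing) and a
#' `transitions` list of `[from, to]` pairs in transition-index order.
#'
#' @param path File path.
#' @return `read_state_space()` returns a `state_space`;
#'   `write_state_space()` returns `path` invisibly.
#' @export
read_state_space <- function(path) {
  y <- yaml::read_yaml(path)
  state_space(states = vapply(y$states, `[[`, 0, "id"),
              labels = vapply(y$states, `[[`, "", "label"),
              absorbing = vapply(y$states, `[[`, TRUE, "absorbing"),
              transitions = do.call(rbind, lapply(y$transitions, unlist)))
}

#' @rdname read_state_space
#' @param space A `state_space` to serialize.
#' @export
write_state_space <- function(space, path) {
  y <- list(
    states = lapply(seq_along(space$states), function(i)
      list(id = space$states[i], label = space$labels[i],
           absorbing = space$absorbing[i])),
    transitions = lapply(seq_len(nrow(space$transitions)), function(k)
      c(space$transitions$from[k], space$transitions$to[k])))
  yaml::write_yaml(y, path)
  invisible(path)
}
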