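#' Stack subject trajectories into transition-specific long format
#'
#' For every sojourn of a subject in a non-absorbing state s over
#' (t_start, t_stop], one row is emitted per allowed transition out of s,
#' sharing (t_start, t_stop); `status` is 1 only on the row of the observed
#' transition, and 0 on every row of a censored sojourn. Under the default
#' clock-forward (Markov) time scale, times are years since diagnosis, so
#' sojourns in later states enter the risk set late (delayed entry /
#' left truncation); under clock-reset, each sojourn is shifted to start
#' at 0 (semi-Markov analysis).
#'
#' @param subjects Wide subject data.frame (see [read_subjects()]).
#' @param space A `state_space`.
#' @param clock `"forward"` (default, Markov) or `"reset"` (semi-Markov).
#' @return A data.frame of class `msm_long` with columns `subject_id`,
#'   `transition`, `from`, `to`, `t_start`, `t_stop`, `status`, then the
#'   covariate columns. Attribute `covariates` carries their names.
#' @export
build_long_format <- function(subjects, space, clock = c("forward", "reset")) {
  clock <- match.arg(clock)
  cols <- subject_columns(subjects, space)
  paths <- subject_paths(subjects, space)
  tr <- space$transitions
  out <- vector("list", length(paths))
  for (i in seq_along(paths)) {
    p <- paths[[i]]
    ns <- length(p$states)
    stop_times <- c(p$times[-1], p$censor)[seq_len(ns)]
    rows <- list()
    for (j in seq_len(ns)) {
      s <- p$states[j]
      ks <- transitions_from(space, s)
      if (!length(ks)) next                      # absorbing: no risk rows
      t0 <- p$times[j]
      t1 <- stop_times[j]
      dest <- if (j < ns) p$states[j + 1] else NA_integer_
      status <- as.integer(!is.na(dest) & tr$to[ks] == dest)
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = p$id, transition = ks,
        from = s, to = tr$to[ks],
        t_start = t0, t_stop = t1, status = status)
    }
    out[[i]] <- do.call(rbind, rows)
  }
  long <- do.call(rbind, out)
  rownames(long) <- NULL
  if (clock == "reset") {
    long$t_stop <- long$t_stop - long$t_start
    long$t_start <- 0
  }
  if (length(cols$covariates)) {
    idx <- match(long$subject_id, subjects$subject_id)
    long <- cbind(long, subjects[idx, cols$covariates, drop = FALSE])
    rownames(long) <- NULL
  }
  structure(long, covariates = cols$covariates, clock = clock,
            class = c("msm_long", "data.frame"))
}

#' Rebuild the wide subject table from long-format rows
#'
#' Inverts [build_long_format()] for clock-forward data: each subject's
#' status-1 rows give the visited states and entry times; a final sojourn
#' with all statuses 0 gives the censoring time.
#'
#' @param long An `msm_long` data.frame (clock-forward).
#' @param space A `state_space`.
#' @return Wide subject data.frame.
#' @export
long_to_subjects <- function(long, space) {
  if (!is.null(attr(long, "clock")) && attr(long, "clock") == "reset")
    stop("round-trip is only defined for clock-forward data")
  covs <- attr(long, "covariates")
  tc <- vapply(setdiff(space$states, first_nonabsorbing(space)), function(s)
    state_time_col(space$labels[match(s, space$states)]), "")
  names(tc) <- setdiff(space$states, first_nonabsorbing(space))
  ids <- unique(long$subject_id)
  rows <- lapply(ids, function(id) {
    li <- long[long$subject_id == id, , drop = FALSE]
    li <- li[order(li$t_start, li$transition), , drop = FALSE]
    w <- stats::setNames(as.list(rep(NA_real_, length(tc))), tc)
    ev <- li[li$status == 1, , drop = FALSE]
    for (r in seq_len(nrow(ev))) w[[tc[as.character(ev$to[r])]]] <- ev$t_stop[r]
    last_stop <- max(li$t_stop)
    absorbed <- nrow(ev) && ev$to[nrow(ev)] %in% space$states[space$absorbing]
    w$time_censor <- if (absorbed) NA_real_ else last_stop
    cbind(data.frame(subject_id = id), as.data.frame(w),
          li[1, covs, drop = FALSE])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Count transitions and end-of-follow-up states
#'
#' Tallies, per transition, the number of subjects observed to make that
#' jump, and per state, the number of subjects ending follow-up there.
#' Each transition count is also expressed as a percentage of the initial
#' cohort size, rounded to one decimal.
#'
#' @inheritParams build_long_format
#' @return List with `transitions` (transition, from, to, n, pct),
#'   `states` (state, label, n_start, n_end) and `n` (cohort size).
#' @export
count_transitions <- function(subjects, space) {
  if (nrow(subjects) == 0) stop("empty cohort")
  paths <- subject_paths(subjects, space)
  n <- length(paths)
  tr <- space$transitions
  key <- paste(tr$from, tr$to)
  cnt <- integer(nrow(tr))
  n_end <- n_start <- integer(length(space$states))
  for (p in paths) {
    st <- p$states
    if (length(st) > 1) {
      pair <- paste(st[-length(st)], st[-1])
      cnt <- cnt + as.integer(key %in% pair)
    }
    n_start[match(st[1], space$states)] <-
      n_start[match(st[1], space$states)] + 1L
    n_end[match(st[length(st)], space$states)] <-
      n_end[match(st[length(st)], space$states)] + 1L
  }
  list(transitions = data.frame(transition = tr$transition, from = tr$from,
                                to = tr$to, n = cnt,
                                pct = round(100 * cnt / n, 1)),
       states = data.frame(state = space$states, label = space$labels,
                           n_start = n_start, n_end = n_end),
       n = n)
}

#' Read or write long-format rows as CSV
#' @param long An `msm_long` data.frame.
#' @param path File path.
#' @export
write_long_format <- function(long, path) {
  utils::write.csv(as.data.frame(long), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_long_format
#' @param covariates Covariate column names (defaults to all columns after
#'   the seven structural ones).
#' @export
read_long_format <- function(path, covariates = NULL) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  fixed <- c("subject_id", "transition", "from", "to",
             "t_start", "t_stop", "status")
  if (is.null(covariates)) covariates <- setdiff(names(x), fixed)
  structure(x, covariates = covariates, clock = "forward",
            class = c("msm_long", "data.frame"))
}
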