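# Wide subject table <-> per-subject trajectories.
#
# The wide format has one row per subject: `subject_id`, covariate columns,
# one `time_<state>` column per non-initial state (years since diagnosis,
# NA if never entered) and `time_censor` (NA if the subject reached an
# absorbing state). State column names strip non-alphanumerics from the
# label, e.g. "overt PMF" -> `time_overtPMF`.

state_time_col <- function(label) {
  paste0("time_", gsub("[^A-Za-z0-9]", "", label))
}

#' Column roles of a wide subject table
#'
#' @param subjects Wide subject data.frame.
#' @param space A `state_space`.
#' @return List with `time_cols` (named by state code) and `covariates`.
#' @keywords internal
subject_columns <- function(subjects, space) {
  noninit <- setdiff(space$states, first_nonabsorbing(space))
  tc <- vapply(noninit, function(s)
    state_time_col(space$labels[match(s, space$states)]), "")
  names(tc) <- noninit
  missing <- setdiff(c(tc, "time_censor", "subject_id"), names(subjects))
  if (length(missing))
    stop("subject table lacks columns: ", paste(missing, collapse = ", "))
  cov <- setdiff(names(subjects), c("subject_id", tc, "time_censor"))
  list(time_cols = tc, covariates = cov)
}

#' Extract validated trajectories from a wide subject table
#'
#' Each subject starts in the initial state at time 0 and visits the states
#' whose `time_*` columns are non-missing, in time order. Entry times must
#' strictly increase, every consecutive pair must be an allowed transition,
#' and a censoring time must lie strictly after the last state entry.
#'
#' @inheritParams subject_columns
#' @return List (one element per subject) of lists with `id`, `states`,
#'   `times`, `censor` (NA if the path ends in an absorbing state).
#' @export
subject_paths <- function(subjects, space) {
  cols <- subject_columns(subjects, space)
  tc <- cols$time_cols
  init <- first_nonabsorbing(space)
  allowed <- paste(space$transitions$from, space$transitions$to)
  absorbing <- space$states[space$absorbing]
  lapply(seq_len(nrow(subjects)), function(i) {
    tv <- vapply(tc, function(cl) as.numeric(subjects[[cl]][i]), 0)
    hit <- !is.na(tv)
    ord <- order(tv[hit])
    st <- c(init, as.integer(names(tc))[hit][ord])
    tm <- unname(c(0, tv[hit][ord]))
    if (any(diff(tm) <= 0))
      stop("subject ", subjects$subject_id[i],
           ": state entry times must strictly increase")
    pair <- paste(st[-length(st)], st[-1])
    bad <- !(pair %in% allowed)
    if (any(bad))
      stop("subject ", subjects$subject_id[i], ": disallowed jump ",
           sub(" ", " -> ", pair[which(bad)[1]]))
    cens <- as.numeric(subjects$time_censor[i])
    last <- st[length(st)]
    if (last %in% absorbing) {
      if (!is.na(cens))
        stop("subject ", subjects$subject_id[i],
             ": censoring time given after absorbing state")
      cens <- NA_real_
    } else {
      if (is.na(cens))
        stop("subject ", subjects$subject_id[i],
             ": non-absorbed subject needs a censoring time")
      if (cens <= tm[length(tm)])
        stop("subject ", subjects$subject_id[i],
             ": censoring time must exceed the last state entry time")
    }
    list(id = subjects$subject_id[i], states = st, times = tm, censor = cens)
  })
}

#' Read or write the wide subject CSV
#'
#' @param path File path.
#' @param space A `state_space` (used to check the schema).
#' @return `read_subjects()` returns the wide data.frame;
#'   `write_subjects()` returns `path` invisibly.
#' @export
read_subjects <- function(path, space) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  subject_columns(x, space)   # schema check
  x
}

#' @rdname read_subjects
#' @param subjects Wide subject data.frame.
#' @export
write_subjects <- function(subjects, path, space) {
  subject_columns(subjects, space)
  utils::write.csv(subjects, path, row.names = FALSE, na = "")
  invisible(path)
}
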