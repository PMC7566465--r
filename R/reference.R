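#' Published transition mix of the pre-PMF registry
#'
#' The per-transition event counts reported for the 382-patient pre-PMF
#' cohort: 58 fibrotic progressions, 18 direct leukemic transformations
#' and 66 direct deaths out of the initial state; 10 leukemic
#' transformations and 14 deaths from overt PMF; 25 deaths after AML.
#'
#' @return data.frame with columns `transition`, `from`, `to`, `n`, plus
#'   attribute `n_total = 382`.
#' @export
pmf_reference_counts <- function() {
  tr <- pmf_state_space()$transitions
  out <- cbind(tr, n = c(58, 18, 66, 10, 14, 25))
  attr(out, "n_total") <- 382L
  out
}

#' Synthetic cohort realizing the published transition mix
#'
#' Builds an event-history table whose per-transition counts equal
#' [pmf_reference_counts()] exactly. Event times are arbitrary
#' placeholders (the counts, not the times, are the published data), so
#' the table supports count/tally arithmetic only, not hazard fitting.
#'
#' @return Wide subject data.frame (no covariate columns).
#' @export
pmf_reference_cohort <- function() {
  blocks <- list(
    # n, time_overtPMF, time_AML, time_death, time_censor
    list(240, NA, NA, NA, 10),   # event-free in pre-PMF
    list(34, 2, NA, NA, 10),     # alive with overt PMF
    list(14, 2, NA, 5, NA),      # died after overt PMF
    list(9, 2, 4, 6, NA),        # overt PMF -> AML -> death
    list(1, 2, 4, NA, 10),       # alive with AML via overt PMF
    list(16, NA, 3, 6, NA),      # direct AML -> death
    list(2, NA, 3, NA, 10),      # alive with AML, direct
    list(66, NA, NA, 4, NA))     # direct death
  rows <- do.call(rbind, lapply(blocks, function(b)
    data.frame(time_overtPMF = rep(b[[2]], b[[1]]), time_AML = b[[3]],
               time_death = b[[4]], time_censor = b[[5]])))
  cbind(data.frame(subject_id = sprintf("R%03d", seq_len(nrow(rows)))),
        rows)
}
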