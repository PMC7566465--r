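# The full replication pipeline: transition counts, clinical vs mutational
# transition-specific fits with AIC comparison, and predicted probability
# curves, consolidated into a report directory.

#' Default covariate families for the replication analysis
#'
#' The clinical family holds the dichotomized clinical risk factors
#' adjusted for three treatment indicators; the mutational family holds
#' the HMR indicator (>= 1 mutated gene among ASXL1, EZH2, SRSF2, IDH1/2)
#' and is fitted on the subcohort with mutation data
#' (`subset_col` = `mut_informative`). Both families model the three
#' direct transitions out of the initial state.
#'
#' @return List with `clinical`, `mutational`, `subset_col`,
#'   `direct_transitions`.
#' @export
default_model_spec <- function() {
  list(clinical = c("age_gt65", "wbc_gt15", "anemia", "fibrosis_g1",
                    "chemo", "antiplatelet", "anticoagulant"),
       mutational = "hmr",
       subset_col = "mut_informative",
       direct_transitions = 1:3)
}

#' Read a model specification from YAML
#' @param path YAML file with keys `clinical`, `mutational`, `subset_col`,
#'   `direct_transitions`.
#' @export
read_model_spec <- function(path) {
  y <- yaml::read_yaml(path)
  spec <- default_model_spec()
  for (nm in names(y)) spec[[nm]] <- unlist(y[[nm]])
  spec
}

fit_or_flag <- function(long, k, covs) {
  tryCatch(fit_transition(long, k, covs),
           error = function(e) structure(list(transition = k,
                                              error = conditionMessage(e)),
                                         class = "failed_fit"))
}

#' Run the full replication analysis
#'
#' Counts transitions, stacks the long format (clock-forward), fits the
#' clinical and mutational covariate families per direct transition,
#' compares them by AIC, fits baseline-only hazards for the remaining
#' transitions, and predicts transition and occupation probability curves
#' by ODE integration and path simulation. Because the mutational family
#' is fitted on the mutation-informative subcohort, the clinical family is
#' additionally refitted on that subcohort so the AIC comparison is also
#' available at equal n.
#'
#' @param subjects Wide subject data.frame, or a path to its CSV.
#' @param space A `state_space`, or a path to its YAML.
#' @param model_spec See [default_model_spec()], or a path to a YAML spec.
#' @param out_dir Output directory (created); NULL to skip file output.
#' @param horizon,grid_n Prediction grid (years, points).
#' @param n_paths Paths for the simulation-based curves.
#' @param seed Seed for the simulation-based curves.
#' @return An `analysis_report` list: `counts`, `fits` (per family),
#'   `aic_table`, `curves`, `occupation`, `meta`.
#' @export
run_registry_analysis <- function(subjects, space = pmf_state_space(),
                               model_spec = default_model_spec(),
                               out_dir = NULL, horizon = 25, grid_n = 101,
                               n_paths = 5000, seed = 1) {
  if (is.character(space)) space <- read_state_space(space)
  if (is.character(subjects)) subjects <- read_subjects(subjects, space)
  if (is.character(model_spec)) model_spec <- read_model_spec(model_spec)
  counts <- count_transitions(subjects, space)
  long <- build_long_format(subjects, space, clock = "forward")
  direct <- model_spec$direct_transitions
  sub_ids <- if (!is.null(model_spec$subset_col) &&
                 model_spec$subset_col %in% names(subjects))
    subjects$subject_id[subjects[[model_spec$subset_col]] == 1]
  else subjects$subject_id
  long_sub <- long[long$subject_id %in% sub_ids, , drop = FALSE]

  families <- list(
    clinical = list(long = long, covs = model_spec$clinical),
    mutational = list(long = long_sub, covs = model_spec$mutational),
    clinical_subcohort = list(long = long_sub, covs = model_spec$clinical))
  fits <- lapply(families, function(fam)
    stats::setNames(lapply(direct, function(k)
      fit_or_flag(fam$long, k, fam$covs)),
      paste0("transition_", direct)))

  aic_rows <- list()
  for (fam in names(fits)) for (nm in names(fits[[fam]])) {
    f <- fits[[fam]][[nm]]
    aic_rows[[length(aic_rows) + 1L]] <- if (inherits(f, "failed_fit"))
      data.frame(transition = f$transition, family = fam, n_rows = NA,
                 n_events = NA, loglik = NA, aic = NA,
                 note = f$error)
    else
      data.frame(transition = f$transition, family = fam,
                 n_rows = f$n_rows, n_events = f$n_events,
                 loglik = f$loglik, aic = stats::AIC(f), note = "")
  }
  aic_table <- do.call(rbind, aic_rows)

  # predictive model: clinical fits on the direct transitions, baseline
  # hazards elsewhere (later-transition covariate models are not part of
  # the replication analysis)
  all_fits <- lapply(seq_len(nrow(space$transitions)), function(k) {
    if (k %in% direct) {
      f <- fits$clinical[[paste0("transition_", k)]]
      if (!inherits(f, "failed_fit")) return(f)
    }
    fit_or_flag(long, k, character())
  })
  failed <- vapply(all_fits, inherits, TRUE, "failed_fit")
  curves <- occupation <- sim_curves <- NULL
  if (!any(failed)) {
    model <- msm_fit(space, all_fits)
    grid <- default_grid(horizon, grid_n)
    occupation <- state_occupation(model, grid, newdata = subjects)
    xbar <- colMeans(subjects[, unique(unlist(
      lapply(all_fits, function(f) f$covariates))), drop = FALSE])
    curves <- transition_probabilities(model, 0, grid, xbar)
    sim_curves <- transition_probabilities(model, 0, grid, xbar,
                                           method = "sim",
                                           n_paths = n_paths, seed = seed)
  }
  # curves out of intermediate states, conditioned on occupancy at the
  # mean observed entry time into the state
  cond_curves <- list()
  if (!any(failed)) {
    paths <- subject_paths(subjects, space)
    mids <- setdiff(space$states[!space$absorbing],
                    first_nonabsorbing(space))
    for (st in mids) {
      entries <- unlist(lapply(paths, function(p)
        p$times[p$states == st]))
      if (!length(entries)) next
      s_a <- mean(entries)
      tg <- grid[grid > s_a + 1e-9]
      if (length(tg) < 2) next
      cond_curves[[space$labels[match(st, space$states)]]] <-
        transition_probabilities(model, s_a, tg, xbar)
    }
  }

  report <- list(counts = counts, fits = fits, aic_table = aic_table,
                 model_fits = all_fits, curves = curves,
                 sim_curves = sim_curves, cond_curves = cond_curves,
                 occupation = occupation,
                 meta = list(n = counts$n, seed = seed,
                             clock = "forward",
                             skipped = which(failed)))
  class(report) <- "analysis_report"
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' Write an analysis report to disk
#'
#' Emits `counts.csv`, `fits_clinical.csv`, `fits_mutational.csv`,
#' `aic.csv`, `curves/ode.csv`, `curves/sim.csv`, `occupation.csv` and a
#' consolidated `report.json`.
#'
#' @param report An `analysis_report`.
#' @param out_dir Output directory (created if needed).
#' @export
write_report <- function(report, out_dir) {
  dir.create(file.path(out_dir, "curves"), recursive = TRUE,
             showWarnings = FALSE)
  utils::write.csv(report$counts$transitions,
                   file.path(out_dir, "counts.csv"), row.names = FALSE)
  for (fam in c("clinical", "mutational")) {
    ok <- Filter(function(f) !inherits(f, "failed_fit"),
                 report$fits[[fam]])
    write_fit_results(ok,
                      csv_path = file.path(out_dir,
                                           paste0("fits_", fam, ".csv")))
  }
  utils::write.csv(report$aic_table, file.path(out_dir, "aic.csv"),
                   row.names = FALSE)
  if (!is.null(report$curves))
    write_curves(report$curves, file.path(out_dir, "curves", "ode.csv"))
  if (!is.null(report$sim_curves))
    write_curves(report$sim_curves, file.path(out_dir, "curves", "sim.csv"))
  for (nm in names(report$cond_curves))
    write_curves(report$cond_curves[[nm]],
                 file.path(out_dir, "curves",
                           paste0("ode_from_",
                                  gsub("[^A-Za-z0-9]", "", nm), ".csv")))
  if (!is.null(report$occupation))
    write_occupation(report$occupation, file.path(out_dir,
                                                  "occupation.csv"))
  jsonlite::write_json(
    list(meta = report$meta,
         counts = report$counts$transitions,
         end_states = report$counts$states,
         aic = report$aic_table),
    file.path(out_dir, "report.json"),
    auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(out_dir)
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("Multistate analysis of", x$meta$n, "subjects\n\nTransitions:\n")
  print(x$counts$transitions)
  cat("\nAIC comparison:\n")
  print(x$aic_table)
  invisible(x)
}
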