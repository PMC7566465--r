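mklong <- function(t_start, t_stop, status, transition = 1) {
  data.frame(transition = transition, t_start = t_start, t_stop = t_stop,
             status = status)
}

test_that("Nelson-Aalen jumps are events over numbers at risk", {
  # single subject, event at 2y: one jump of size 1
  na1 <- nelson_aalen(mklong(0, 2, 1), 1)
  expect_equal(na1$jump_times, 2)
  expect_equal(na1$values, 1)
  # 2 tied events among 10 at risk: jump 0.2
  long <- mklong(rep(0, 10), c(rep(2, 2), rep(5, 8)),
                 c(1, 1, rep(0, 8)))
  na2 <- nelson_aalen(long, 1)
  expect_equal(na2$increments[1], 0.2)
  # no events: flat zero
  na0 <- nelson_aalen(mklong(0, 2, 0), 1)
  expect_length(na0$jump_times, 0)
  expect_equal(step_curve_at(na0, c(1, 5)), c(0, 0))
})

test_that("risk sets honour delayed entry", {
  # the subject entering at t = 3 is not at risk for the event at t = 2
  long <- mklong(c(0, 0, 3), c(2, 6, 6), c(1, 1, 1))
  na <- nelson_aalen(long, 1)
  expect_equal(na$jump_times, c(2, 6))
  expect_equal(na$increments, c(1 / 2, 2 / 2))
})

test_that("Nelson-Aalen tracks the true cumulative hazard of an
           exponential simulation", {
  mu <- 0.15
  cfg <- cohort_config(8000, two_state_space(), shapes = 1, rates = mu,
                       admin_horizon = 12, dropout_rate = 0.05,
                       seed = 31)
  long <- build_long_format(generate_cohort(cfg), cfg$space)
  na <- nelson_aalen(long, 1)
  for (t in c(2, 5, 9)) {
    est <- step_curve_at(na, t)
    keep <- na$jump_times <= t
    # Poisson-type variance: sum d / Y^2 = sum increments^2 / d
    d <- vapply(na$jump_times[keep], function(tt)
      sum(long$status == 1 & long$t_stop == tt &
            long$transition == 1), 0)
    se <- sqrt(sum(na$increments[keep]^2 / d))
    expect_lt(abs(est - mu * t), 3 * se)
  }
})

test_that("Aalen-Johansen with no events is the identity at all times", {
  long <- build_long_format(
    data.frame(subject_id = c("a", "b"), time_overtPMF = NA, time_AML = NA,
               time_death = NA, time_censor = c(4, 6)),
    pmf_state_space())
  aj <- aalen_johansen(long, pmf_state_space(), 0, c(1, 5))
  expect_equal(aj$P[1, , ], diag(4), ignore_attr = TRUE)
  expect_equal(aj$P[2, , ], diag(4), ignore_attr = TRUE)
})

test_that("in the two-state model Aalen-Johansen equals one minus
           Kaplan-Meier exactly", {
  skip_if_not_installed("survival")
  set.seed(41)
  n <- 200
  t1 <- rweibull(n, 1.2, 5)
  cens <- runif(n, 1, 8)
  coh <- data.frame(subject_id = seq_len(n),
                    time_dead = ifelse(t1 <= cens, t1, NA),
                    time_censor = ifelse(t1 <= cens, NA, cens))
  ss <- two_state_space()
  long <- build_long_format(coh, ss)
  times <- c(1, 2, 4, 6)
  aj <- aalen_johansen(long, ss, 0, times)
  km <- survival::survfit(
    survival::Surv(long$t_stop, long$status) ~ 1)
  km_at <- summary(km, times = times)$surv
  expect_equal(aj$P[, 1, 1], km_at, tolerance = 1e-12)
  expect_equal(aj$P[, 1, 2], 1 - km_at, tolerance = 1e-12)
})

test_that("multistate Aalen-Johansen matches survival::survfit's
           multistate estimator", {
  skip_if_not_installed("survival")
  cfg <- plain_weibull_config(n = 600, seed = 17)
  coh <- generate_cohort(cfg)
  space <- cfg$space
  long <- build_long_format(coh, space)
  times <- c(2, 5, 10, 15)
  aj <- aalen_johansen(long, space, 0, times)
  # sojourn-level data for survfit: one row per sojourn, destination as a
  # factor level (censor = first level)
  paths <- subject_paths(coh, space)
  soj <- do.call(rbind, lapply(paths, function(p) {
    ns <- length(p$states)
    stops <- c(p$times[-1], p$censor)[seq_len(ns)]
    keep <- !space$absorbing[match(p$states, space$states)]
    data.frame(id = p$id, t0 = p$times[keep], t1 = stops[keep],
               to = c(p$states[-1], NA)[keep])
  }))
  soj$ev <- factor(ifelse(is.na(soj$to), "censor", soj$to),
                   levels = c("censor", "2", "3", "4"))
  fit <- survival::survfit(survival::Surv(t0, t1, ev) ~ 1, data = soj,
                           id = id)
  sm <- summary(fit, times = times)
  ref <- sm$pstate[, match(c("(s0)", "2", "3", "4"), fit$states)]
  expect_equal(unname(aj$P[, 1, ]), unname(ref), tolerance = 1e-8)
})

test_that("Aalen-Johansen rows sum to one exactly and estimate the true
           model probabilities on simulated data", {
  cfg <- plain_weibull_config(n = 4000, seed = 23)
  coh <- generate_cohort(cfg)
  long <- build_long_format(coh, cfg$space)
  times <- c(5, 10, 15)
  aj <- aalen_johansen(long, cfg$space, 0, times)
  sums <- apply(aj$P, c(1, 2), sum)
  expect_equal(sums, matrix(1, 3, 4), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_true(all(aj$P >= 0 & aj$P <= 1))
  truth <- transition_probabilities(config_model(cfg), 0, times)
  # bootstrap over subjects for the standard error of the estimate
  set.seed(5)
  B <- 30
  boot <- array(NA_real_, c(B, 3, 4))
  ids <- unique(long$subject_id)
  for (b in seq_len(B)) {
    take <- sample(ids, replace = TRUE)
    idx <- unlist(lapply(take, function(i)
      which(long$subject_id == i)), use.names = FALSE)
    bl <- long[idx, ]
    boot[b, , ] <- aalen_johansen(bl, cfg$space, 0, times)$P[, 1, ]
  }
  se <- apply(boot, c(2, 3), sd)
  diffs <- abs(aj$P[, 1, ] - truth$P[, 1, ])
  expect_true(all(diffs <= 3 * se + 1e-9))
})
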