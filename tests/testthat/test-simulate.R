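test_that("calibrated defaults encode the published summaries", {
  m <- default_true_model()
  Q <- build_generator(m$params)
  expect_equal(round(Q[1, 2] / Q[1, 3], 2), 11.08)
  expect_equal(1 / (-Q[3, 3]), 2.51, tolerance = 1e-12)
  expect_true(all(exp(m$params$log_q0) > 0))
  expect_true(is_progressive(m$structure))
  expect_identical(m$effects, "none")
  # effect presets attach coefficients without moving the baselines
  m15 <- default_true_model(effects = "hr15")
  expect_equal(m15$params$log_q0, m$params$log_q0)
  expect_equal(exp(m15$params$beta[["1>2"]][["x"]]), 1.5)
  mt3 <- default_true_model(effects = "published-hr")
  expect_equal(exp(mt3$params$beta[["1>2"]][["age_c"]]), 1.05)
  expect_equal(exp(mt3$params$beta[["2>4"]][["heart_problem"]]), 1.62)
})

test_that("subject simulation is deterministic per seed and respects rates", {
  m <- default_true_model()
  t1 <- simulate_subject(m, seed = 7)
  t2 <- simulate_subject(m, seed = 7)
  expect_identical(t1, t2)
  t3 <- simulate_subject(m, seed = 8)
  expect_false(identical(t1, t3))
  expect_equal(t1$time[1], 0)
  expect_equal(t1$state[1], 1L)
  # all rates zero: the subject never leaves State 1
  z <- ltc_params(m$structure,
                  q0 = stats::setNames(rep(1e-12, 6), m$structure$keys))
  frozen <- simulate_subject(z, horizon = 10, seed = 1)
  expect_identical(nrow(frozen), 1L)
})

test_that("cohort simulation is reproducible and covariates match design", {
  m <- default_true_model()
  c1 <- simulate_cohort(m, n = 500, seed = 31)
  c2 <- simulate_cohort(m, n = 500, seed = 31)
  expect_identical(c1$trajectories, c2$trajectories)
  expect_identical(c1$covariates, c2$covariates)
  cv <- c1$covariates
  expect_true(all(cv$age >= 75 & cv$age <= 82))
  expect_true(all(cv$widowed %in% 0:1))
  # marginal prevalences within 3 binomial SEs of the design values
  design <- c(area_regional = 0.567, widowed = 0.459,
              income_difficulty = 0.256, arthritis = 0.488,
              heart_problem = 0.191, diabetes = 0.096, asthma = 0.133,
              falls_injury = 0.123)
  for (nm in names(design)) {
    se <- sqrt(design[[nm]] * (1 - design[[nm]]) / 500)
    expect_lt(abs(mean(cv[[nm]]) - design[[nm]]), 3 * se)
  }
})

test_that("empirical occupancy matches the closed-form exit law", {
  m <- default_true_model()
  cohort <- simulate_cohort(m, n = 8000, seed = 37)
  occ <- states_at(cohort, 10)
  p_hat <- mean(occ == 1L)
  p_true <- exp(-10 / 7.95)
  expect_lt(abs(p_hat - p_true), 3 * sqrt(p_true * (1 - p_true) / 8000))
  # censoring-corrected mean exit time: the holding time is exponential,
  # so its censored-likelihood estimate 1/q = person-years / exits
  # should recover the 7.95-year mean stay
  py <- vapply(cohort$trajectories, function(tr)
    min(tr$time[2], 10, na.rm = TRUE), 0)
  exits <- vapply(cohort$trajectories, function(tr) nrow(tr) > 1L, TRUE)
  q_hat <- sum(exits) / sum(py)
  se_log <- 1 / sqrt(sum(exits))
  expect_lt(abs(log(q_hat) - log(1 / 7.95)), 3 * se_log)
})

test_that("observation schemes map trajectories to valid panels", {
  m <- default_true_model()
  # censored subject on a 3-yearly grid: snapshots at 0, 3, 6, 9
  one <- structure(list(
    trajectories = list(data.frame(time = 0, state = 1L)),
    covariates = data.frame(subject_id = "S1"),
    model = m, seed = 1), class = "ltc_cohort")
  obs <- observe_cohort(one, "panel-3yr")
  expect_equal(obs$time, c(0, 3, 6, 9))
  expect_true(all(obs$state == "Non-user"))
  expect_true(all(obs$obs_type == "snapshot"))

  # dated care entry then death under the exact scheme
  two <- structure(list(
    trajectories = list(data.frame(time = c(0, 2.4, 7.1),
                                   state = c(1L, 2L, 4L))),
    covariates = data.frame(subject_id = "S1"),
    model = m, seed = 1), class = "ltc_cohort")
  obs2 <- observe_cohort(two, "exact")
  expect_equal(obs2$time, c(0, 2.4, 7.1))
  expect_equal(obs2$state, c("Non-user", "HACC", "Death"))
  expect_equal(obs2$obs_type,
               c("snapshot", "exact_transition", "exact_transition"))
  # the unknown-pre-death convention types the death row exact_death
  obs3 <- observe_cohort(two, "exact", death_obs = "unknown")
  expect_equal(obs3$obs_type,
               c("snapshot", "exact_transition", "exact_death"))
  # grid scheme keeps death exact and drops post-death snapshots
  obs4 <- observe_cohort(two, "panel-3yr")
  expect_equal(obs4$time, c(0, 3, 6, 7.1))
  expect_equal(obs4$state, c("Non-user", "HACC", "HACC", "Death"))
  expect_equal(obs4$obs_type[4], "exact_death")
})

test_that("frequency tables agree between trajectories and observations", {
  m <- default_true_model()
  cohort <- simulate_cohort(m, n = 400, seed = 41)
  panel <- observe_cohort(cohort, "exact")
  tab <- multistate_frequency_table(panel)
  # recompute directly from the exact trajectories
  n_states <- length(m$structure$states)
  tab2 <- matrix(0L, n_states, n_states)
  for (tr in cohort$trajectories) {
    st <- tr$state
    if (length(st) > 1L)
      for (j in seq_len(length(st) - 1L))
        tab2[st[j], st[j + 1L]] <- tab2[st[j], st[j + 1L]] + 1L
    last <- st[length(st)]
    tab2[last, last] <- tab2[last, last] + 1L
  }
  expect_equal(unname(unclass(tab)), tab2, ignore_attr = TRUE)
})
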