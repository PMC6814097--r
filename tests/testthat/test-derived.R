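test_that("transition rate ratios follow the printed State-1 calibration", {
  Q <- default_Q()
  expect_identical(transition_rate_ratio(Q, "1>2", "1>2")$value, 1)
  # calibrated defaults reproduce the published State-1 rate ratios
  expect_equal(round(transition_rate_ratio(Q, "1>2", "1>3")$value, 2),
               11.08)
  expect_equal(round(transition_rate_ratio(Q, "1>2", "1>4")$value, 2),
               7.72)
  # ratio algebra: TRR(a vs b) = TRR(a vs c) / TRR(b vs c)
  set.seed(21)
  for (rep in 1:5) {
    Qr <- random_progressive_Q()
    lhs <- transition_rate_ratio(Qr, "1>2", "1>3")$value
    rhs <- transition_rate_ratio(Qr, "1>2", "1>4")$value /
      transition_rate_ratio(Qr, "1>3", "1>4")$value
    expect_equal(lhs, rhs, tolerance = 1e-12)
  }
  Q0 <- Q; Q0[1, 3] <- 0
  expect_error(transition_rate_ratio(Q0, "1>2", "1>3"),
               class = "ltc_domain_error")
})

test_that("next-state probabilities are the embedded jump-chain weights", {
  # two equal exits split 50/50
  Q <- matrix(0, 3, 3); Q[1, 2] <- Q[1, 3] <- 0.4
  diag(Q) <- -rowSums(Q)
  expect_equal(unname(next_state_probabilities(Q, 1)), c(0.5, 0.5))
  # rates in the printed ratios 1 : 1/11.08 : 1/7.72 give .82/.07/.11
  Q <- matrix(0, 4, 4)
  Q[1, 2] <- 1; Q[1, 3] <- 1 / 11.08; Q[1, 4] <- 1 / 7.72
  diag(Q) <- -rowSums(Q)
  p <- next_state_probabilities(Q, 1)
  expect_equal(sum(p), 1, tolerance = 1e-12)
  expect_equal(unname(round(p, 2)), c(0.82, 0.07, 0.11))
  # the printed HACC ratio 1.69 gives .63/.37
  Q2 <- matrix(0, 3, 3); Q2[1, 2] <- 1.69; Q2[1, 3] <- 1
  diag(Q2) <- -rowSums(Q2)
  expect_equal(unname(round(next_state_probabilities(Q2, 1), 2)),
               c(0.63, 0.37))
  expect_error(next_state_probabilities(Q2, 3),
               class = "ltc_domain_error")
})

test_that("mean sojourn time inverts the total exit rate", {
  Q <- default_Q()
  expect_equal(mean_sojourn_time(Q, 1), 7.95, tolerance = 1e-12)
  expect_equal(mean_sojourn_time(Q, 2), 5.04, tolerance = 1e-12)
  expect_equal(mean_sojourn_time(Q, 3), 2.51, tolerance = 1e-12)
  expect_equal(mean_sojourn_time(two_state_Q(0.5), 1), 2.0)
  # doubling every rate halves every sojourn
  expect_equal(mean_sojourn_time(2 * Q, 1), 7.95 / 2)
  expect_error(mean_sojourn_time(Q, 4), class = "ltc_domain_error")
})

test_that("total length of stay matches closed forms and quadrature", {
  lam <- 1 / 7.95
  Q2 <- two_state_Q(lam)
  expect_equal(total_length_of_stay(Q2, 1, 1, Inf), 1 / lam,
               tolerance = 1e-10)
  expect_equal(total_length_of_stay(Q2, 1, 1, 10),
               (1 - exp(-10 * lam)) / lam, tolerance = 1e-8)
  # trapezoid oracle on the calibrated defaults
  Q <- default_Q()
  grid <- seq(0, 10, by = 1e-3)
  fac <- ltcmarkov:::tpm_factory(Q)
  vals <- fac$entry(1, 2, grid)
  trap <- sum((vals[-1] + vals[-length(vals)]) / 2) * 1e-3
  expect_equal(total_length_of_stay(Q, 1, 2, 10), trap, tolerance = 1e-5)
  expect_error(total_length_of_stay(Q, 1, 4, Inf),
               class = "ltc_domain_error")
})

test_that("survival probability complements the absorption probability", {
  Q <- default_Q()
  expect_equal(survival_probability(Q, 1, 0), 1)
  expect_equal(survival_probability(Q, 4, c(1, 5)), c(0, 0))
  # single-exit closed form from RAC
  expect_equal(survival_probability(Q, 3, 10), exp(-10 * Q[3, 4]),
               tolerance = 1e-10)
  # non-increasing in t for the progressive structure
  s <- survival_probability(Q, 1, seq(0, 20, by = 0.5))
  expect_true(all(diff(s) <= 1e-12))
})

test_that("frequency table counts next-entered states and survivors", {
  panel <- make_panel(list(
    a = list(list(0, "Non-user", "snapshot"),
             list(1, "HACC", "exact_transition"),
             list(3, "Death", "exact_transition")),
    b = list(list(0, "Non-user", "snapshot"),
             list(10, "Non-user", "snapshot")),
    d = list(list(0, "Non-user", "snapshot"),
             list(4, "RAC", "exact_transition"),
             list(10, "RAC", "snapshot"))))
  tab <- multistate_frequency_table(panel)
  expect_equal(unname(tab[1, ]), c(1, 1, 1, 0))
  expect_equal(unname(tab[2, ]), c(0, 0, 0, 1))
  expect_equal(unname(tab[3, ]), c(0, 0, 1, 0))
  expect_equal(unname(attr(tab, "ever")), c(3, 1, 1, 1))

  # all-censored cohort: everyone stays on the diagonal
  censored <- make_panel(list(
    x = list(list(0, "Non-user", "snapshot"),
             list(10, "Non-user", "snapshot")),
    y = list(list(0, "Non-user", "snapshot"),
             list(10, "Non-user", "snapshot"))))
  expect_equal(unname(diag(multistate_frequency_table(censored))),
               c(2, 0, 0, 0))

  # conservation on simulated data: rows sum to their 'ever' totals and
  # inbound counts match each state's total visits
  panel2 <- quick_panel(n = 200, seed = 13)
  tab2 <- multistate_frequency_table(panel2)
  ever <- attr(tab2, "ever")
  expect_equal(rowSums(tab2), ever)
  for (j in 2:4)
    expect_equal(sum(tab2[-j, j]), unname(ever[j]))
  expect_equal(unname(ever[1]), n_subjects(panel2))
})

test_that("prevalence series conserves the cohort and starts in State 1", {
  panel <- quick_panel(n = 150, seed = 17)
  prev <- prevalence_gof(default_params(), panel, times = 0:10)
  n <- attr(prev, "n")
  expect_identical(n, 150L)
  for (t in unique(prev$time)) {
    sl <- prev[prev$time == t, ]
    expect_equal(sum(sl$observed), n)
    expect_equal(sum(sl$expected), n, tolerance = 1e-6)
  }
  at0 <- prev[prev$time == 0, ]
  expect_equal(at0$observed, c(n, 0, 0, 0))
  expect_equal(at0$expected, c(n, 0, 0, 0), tolerance = 1e-9)
  expect_error(prevalence_gof(default_params(), panel, times = c(-1, 2)),
               class = "ltc_domain_error")
})

test_that("summary table carries ratios, probabilities and sojourns with CIs", {
  m <- default_true_model()
  panel <- observe_cohort(simulate_cohort(m, n = 600, seed = 23))
  fit <- ltc_fit(panel)
  summ <- transition_summary(fit)
  expect_true(all(c("TRR", "next_state_probability", "sojourn") %in%
                    summ$quantity))
  ok <- !is.na(summ$lower)
  expect_true(all(summ$lower[ok] <= summ$value[ok] + 1e-10))
  expect_true(all(summ$value[ok] <= summ$upper[ok] + 1e-10))
  probs <- summ[summ$quantity == "next_state_probability", ]
  from1 <- grepl("^from Non-user", probs$description)
  expect_equal(sum(probs$value[from1]), 1, tolerance = 1e-12)
  # display formatting rounds to 2 dp
  disp <- format_summary_table(summ)
  expect_true(all(grepl("^[0-9.]+$", disp$value)))
})
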