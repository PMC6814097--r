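test_that("intercept-only fit recovers the generating rates", {
  m <- default_true_model()
  panel <- observe_cohort(simulate_cohort(m, n = 1500, seed = 2))
  fit <- ltc_fit(panel)
  expect_true(fit$converged)
  expect_length(fit$theta, 6L)
  # covariance symmetric positive semi-definite
  expect_equal(fit$cov, t(fit$cov), tolerance = 1e-8)
  expect_true(all(eigen(fit$cov, only.values = TRUE)$values > -1e-8))
  truth <- m$params$log_q0
  se <- sqrt(diag(fit$cov))
  expect_true(all(abs(fit$theta[1:6] - truth) < 3 * se))
  # likelihood at the optimum has a (numerically) vanishing gradient
  expect_lt(fit$grad_norm, 1e-4 * (1 + abs(fit$loglik)))
  # reported likelihood is reproducible from the estimates
  expect_equal(dataset_log_likelihood(panel, fitted_params(fit)),
               fit$loglik, tolerance = 1e-8)
})

test_that("a binary covariate effect is recovered with its hazard ratio", {
  m <- default_true_model(effects = "hr15")
  panel <- observe_cohort(simulate_cohort(m, n = 1500, seed = 3))
  fit <- ltc_fit(panel, formulas = list("1>2" = "x"))
  expect_true(fit$converged)
  hr <- hazard_ratios(fit, "1>2", "x")
  expect_equal(nrow(hr), 1L)
  # true hazard ratio 1.5 within 3 delta-method SEs
  expect_lt(abs(hr$hr - 1.5), 3 * hr$hr * hr$se_log)
  expect_true(hr$lower < hr$hr & hr$hr < hr$upper)
})

test_that("hazard-ratio intervals follow the closed Wald form", {
  # synthetic fit object: beta-hat = 0 with SE 0.1 -> HR 1.00 (0.822, 1.217)
  s <- ltc_structure(states = c("A", "B"), transitions = "1>2")
  skel <- ltcmarkov:::theta_skeleton(s, list("1>2" = "x"))
  fit <- structure(list(
    theta = stats::setNames(c(log(0.2), 0), skel$names),
    cov = diag(c(0.05^2, 0.1^2)), loglik = 0, converged = TRUE,
    niter = 0L, grad_norm = 0, n_subjects = 0L, n_obs = 0L,
    structure = s, formulas = list("1>2" = "x"), skeleton = skel),
    class = "ltc_fit")
  dimnames(fit$cov) <- list(skel$names, skel$names)
  hr <- hazard_ratios(fit)
  expect_equal(hr$hr, 1)
  expect_equal(round(hr$lower, 3), 0.822)
  expect_equal(round(hr$upper, 3), 1.217)
  # degenerate SE = 0 gives the point interval (1, 1)
  fit0 <- fit
  fit0$cov[2, 2] <- 0
  hr0 <- hazard_ratios(fit0)
  expect_equal(c(hr0$lower, hr0$hr, hr0$upper), c(1, 1, 1))
  expect_error(hazard_ratios(fit, transitions = "9>9"), "transition")
  expect_error(hazard_ratios(fit, "1>2", covariates = "unknown_cov"),
               "covariate")
})

test_that("delta method is exact for linear maps and consistent elsewhere", {
  s <- ltc_structure(states = c("A", "B"), transitions = "1>2")
  skel <- ltcmarkov:::theta_skeleton(s, list("1>2" = "x"))
  Sig <- diag(2)
  fit <- structure(list(
    theta = stats::setNames(c(0.4, -0.3), skel$names), cov = Sig,
    loglik = 0, converged = TRUE, niter = 0L, grad_norm = 0,
    n_subjects = 0L, n_obs = 0L, structure = s,
    formulas = list("1>2" = "x"), skeleton = skel), class = "ltc_fit")

  # linear map: exact normal interval
  a <- c(2, -1)
  dm <- delta_method_ci(fit, function(th) sum(a * th))
  exact_se <- sqrt(as.numeric(t(a) %*% Sig %*% a))
  expect_equal(dm$se, exact_se, tolerance = 1e-8)
  expect_equal(dm$lower, sum(a * fit$theta) - 1.96 * exact_se,
               tolerance = 1e-8)

  # difference of two coordinates under identity covariance: SE = sqrt(2)
  dm2 <- delta_method_ci(fit, function(th) th[1] - th[2])
  expect_equal(dm2$se, sqrt(2), tolerance = 1e-8)

  # g = exp(theta_k) with the log-scale interval reproduces hazard_ratios
  hr <- hazard_ratios(fit)
  dm3 <- delta_method_ci(fit, function(th) exp(th[2]), transform = "log")
  expect_equal(dm3$estimate, hr$hr, tolerance = 1e-10)
  expect_equal(dm3$lower, hr$lower, tolerance = 1e-6)
  expect_equal(dm3$upper, hr$upper, tolerance = 1e-6)
})

test_that("never-observed transitions raise a boundary diagnostic", {
  # trajectories that never use RAC leave 2>3 and 3>4 unobserved
  panel <- make_panel(list(
    a = list(list(0, "Non-user", "snapshot"),
             list(2, "HACC", "exact_transition"),
             list(10, "HACC", "snapshot")),
    b = list(list(0, "Non-user", "snapshot"),
             list(10, "Non-user", "snapshot")),
    d = list(list(0, "Non-user", "snapshot"),
             list(1, "HACC", "exact_transition"),
             list(4, "Death", "exact_transition"))))
  warns <- character()
  withCallingHandlers(
    fit <- ltc_fit(panel, control = list(maxit = 200)),
    warning = function(w) {
      warns <<- c(warns, class(w)[1L]); invokeRestart("muffleWarning")
    })
  expect_true("ltc_boundary_warning" %in% warns)
})

test_that("snapshot and exact observation of one cohort agree within 2 SE", {
  m <- default_true_model()
  cohort <- simulate_cohort(m, n = 800, seed = 9)
  fit_exact <- ltc_fit(observe_cohort(cohort, "exact"))
  fit_panel <- ltc_fit(observe_cohort(cohort, "panel-6mo"))
  se <- sqrt(diag(fit_exact$cov))
  expect_true(all(abs(fit_exact$theta - fit_panel$theta) < 2 * se))
})

test_that("formula presets resolve against available covariates", {
  panel <- quick_panel(n = 30, seed = 1)
  f <- resolve_formulas("main", attr(panel, "structure"),
                        setdiff(names(panel),
                                c("subject_id", "time", "state", "obs_type",
                                  "state_idx")))
  expect_length(f, 6L)
  expect_true(all(vapply(f, function(x) "age" %in% x, TRUE)))
  expect_error(resolve_formulas("health-adjusted", attr(panel, "structure"),
                                "age"),
               "health")
  expect_error(resolve_formulas("nonsense", attr(panel, "structure"), "age"),
               "preset")
  expect_error(resolve_formulas(list("1>2" = "missing_cov"),
                                attr(panel, "structure"), "age"),
               "missing_cov")
})
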