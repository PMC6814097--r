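# --- parameter vector packing -----------------------------------------------

# The unconstrained parameter vector theta stacks, in structure order, the
# log baseline intensities of every allowed transition, followed by the
# covariate coefficients of each transition in formula order.
theta_skeleton <- function(structure, formulas) {
  nms <- paste0("logq(", structure$keys, ")")
  for (key in structure$keys) {
    f <- formulas[[key]]
    if (length(f)) nms <- c(nms, paste0("beta(", key, "):", f))
  }
  list(structure = structure, formulas = formulas, names = nms,
       n_trans = length(structure$keys))
}

theta_pack <- function(params, skel) {
  th <- unname(params$log_q0[skel$structure$keys])
  for (key in skel$structure$keys) {
    f <- skel$formulas[[key]]
    if (length(f)) {
      b <- params$beta[[key]]
      th <- c(th, unname(b[f]))
    }
  }
  stats::setNames(th, skel$names)
}

theta_unpack <- function(theta, skel) {
  nt <- skel$n_trans
  q0 <- stats::setNames(exp(theta[seq_len(nt)]), skel$structure$keys)
  beta <- list()
  pos <- nt
  for (key in skel$structure$keys) {
    f <- skel$formulas[[key]]
    if (length(f)) {
      beta[[key]] <- stats::setNames(theta[pos + seq_along(f)], f)
      pos <- pos + length(f)
    }
  }
  ltc_params(skel$structure, q0, beta)
}

# --- model formulas ----------------------------------------------------------

main_model_covariates <- c("age", "area_regional", "widowed",
                           "income_difficulty", "arthritis", "heart_problem",
                           "diabetes", "asthma", "falls_injury")
demographic_covariates <- c("age", "area_regional", "widowed",
                            "income_difficulty")

#' Resolve per-transition covariate formulas
#'
#' Model presets mirror the two-tier covariate strategy of the study this
#' package emulates: `"main"` enters the demographic factors, chronic
#' conditions and falls simultaneously on every transition;
#' `"health-adjusted"` enters one health indicator (self-rated health or an
#' SF-36 domain) adjusted only for the demographic factors;
#' `"intercept-only"` fits baseline intensities alone.
#'
#' @param formulas A preset name (`"intercept-only"`, `"main"`,
#'   `"health-adjusted"`) or a named list mapping transition keys
#'   (`"1>2"` style) to character vectors of covariate names. Transitions
#'   absent from the list get no covariates.
#' @param structure An [ltc_structure()].
#' @param data_covariates Covariate column names available in the data.
#' @param health For `"health-adjusted"`: name of the single health
#'   indicator covariate.
#' @return Named list, one character vector per transition key.
#' @export
resolve_formulas <- function(formulas, structure, data_covariates,
                             health = NULL) {
  if (is.character(formulas) && length(formulas) == 1L) {
    preset <- formulas
    covs <- switch(preset,
      "intercept-only" = character(0),
      "main" = main_model_covariates,
      "health-adjusted" = {
        if (is.null(health))
          stop("preset 'health-adjusted' needs `health = <covariate name>`",
               call. = FALSE)
        c(demographic_covariates, health)
      },
      stop("unknown preset '", preset, "'; use intercept-only, main or ",
           "health-adjusted", call. = FALSE))
    missing_cv <- setdiff(covs, data_covariates)
    if (length(missing_cv))
      stop("preset '", preset, "' needs covariate column(s) not in data: ",
           paste(missing_cv, collapse = ", "), call. = FALSE)
    formulas <- stats::setNames(rep(list(covs), length(structure$keys)),
                                structure$keys)
  } else if (is.list(formulas)) {
    extra <- setdiff(names(formulas), structure$keys)
    if (length(extra))
      stop("formula keys not in structure: ", paste(extra, collapse = ", "),
           call. = FALSE)
    missing_cv <- setdiff(unique(unlist(formulas)), data_covariates)
    if (length(missing_cv))
      stop("formula covariate(s) not in data: ",
           paste(missing_cv, collapse = ", "), call. = FALSE)
    full <- stats::setNames(rep(list(character(0)), length(structure$keys)),
                            structure$keys)
    full[names(formulas)] <- lapply(formulas, as.character)
    formulas <- full
  } else stop("`formulas` must be a preset name or a named list",
              call. = FALSE)
  formulas
}

# --- crude initial values ----------------------------------------------------

# Crude rates: observed i->j events divided by person-years observed in i.
# Snapshot state changes count as one direct event; exact deaths are
# attributed to the last known state. Always feasible, scale-free start.
crude_rates <- function(iv, structure) {
  n <- length(structure$states)
  events <- matrix(0, n, n)
  py <- numeric(n)
  for (k in seq_along(iv$dt)) py[iv$from[k]] <- py[iv$from[k]] + iv$dt[k]
  move <- iv$from != iv$to
  if (any(move)) {
    tab <- table(factor(iv$from[move], levels = seq_len(n)),
                 factor(iv$to[move], levels = seq_len(n)))
    events <- events + unclass(tab)
  }
  keys <- structure$keys
  al <- structure$allowed
  ev <- events[al]
  q0 <- pmax(ev, 0.5) / pmax(py[al[, 1L]], 1e-8)
  list(q0 = stats::setNames(pmin(pmax(q0, 1e-6), 1e3), keys),
       events = stats::setNames(ev, keys))
}

# --- model fitting -----------------------------------------------------------

#' Fit a continuous-time multi-state model by maximum likelihood
#'
#' Maximises [dataset_log_likelihood()] over the unconstrained parameter
#' vector (log baseline intensities, raw covariate coefficients) by
#' quasi-Newton (BFGS) ascent. The covariance of the estimate is the
#' inverse of the observed information, obtained by central finite
#' differencing of the log-likelihood at the maximum.
#'
#' Initial values are crude rates — observed i>j events per person-year in
#' state i — with all coefficients zero, unless `init` supplies a starting
#' [ltc_params()]. A structurally allowed transition with no observed
#' events triggers a boundary diagnostic (warning class
#' `ltc_boundary_warning`): its intensity is weakly identified and will
#' drift towards zero.
#'
#' @param data An [ltc_panel()].
#' @param formulas Model preset or per-transition covariate lists; see
#'   [resolve_formulas()].
#' @param init Optional [ltc_params()] with starting values.
#' @param health Health indicator name for the `"health-adjusted"` preset.
#' @param control List of optimizer settings: `maxit` (default 500),
#'   `reltol` (1e-10), `grad_tol` — convergence requires the largest
#'   absolute central-difference gradient component below
#'   `grad_tol * (1 + |logLik|)` (default factor 1e-4).
#'
#' @return Object of class `ltc_fit`: elements `theta` (named estimates),
#'   `cov` (covariance of theta, `NULL` if the information matrix was
#'   singular), `loglik`, `converged`, `niter`, `grad_norm`,
#'   `n_subjects`, `n_obs`, `structure`, `formulas`, `skeleton`.
#'
#' @seealso [hazard_ratios()], [delta_method_ci()], [transition_summary()]
#' @export
ltc_fit <- function(data, formulas = "intercept-only", init = NULL,
                    health = NULL, control = list()) {
  stopifnot(inherits(data, "ltc_panel"))
  structure <- attr(data, "structure")
  ctrl <- utils::modifyList(list(maxit = 500L, reltol = 1e-10,
                                 grad_tol = 1e-4), control)
  reserved <- c("subject_id", "time", "state", "obs_type", "state_idx")
  data_covs <- setdiff(names(data), reserved)
  formulas <- resolve_formulas(formulas, structure, data_covs, health)
  skel <- theta_skeleton(structure, formulas)

  iv <- panel_intervals(data)
  if (!length(iv$dt)) stop("no observation intervals to fit", call. = FALSE)
  if (any(iv$dt <= 0)) stop("non-positive interval length", call. = FALSE)

  crude <- crude_rates(iv, structure)
  zero_ev <- names(crude$events)[crude$events == 0]
  if (length(zero_ev))
    warning(warningCondition(
      paste0("allowed transition(s) never observed: ",
             paste(zero_ev, collapse = ", "),
             "; baseline intensity weakly identified (boundary)"),
      class = "ltc_boundary_warning"))

  if (is.null(init)) {
    init <- ltc_params(structure, crude$q0,
                       lapply(formulas[lengths(formulas) > 0L],
                              function(f) stats::setNames(rep(0, length(f)),
                                                          f)))
  }
  theta0 <- theta_pack(init, skel)

  pats <- interval_patterns(data, theta_unpack(theta0, skel), iv = iv)
  negll <- function(theta) {
    val <- tryCatch({
      p <- theta_unpack(theta, skel)
      as.numeric(ll_compute(iv, pats$pat, pats$Z, p))
    }, error = function(e) -Inf)
    if (!is.finite(val)) return(1e10)
    -val
  }

  opt <- stats::optim(theta0, negll, method = "BFGS",
                      control = list(maxit = ctrl$maxit,
                                     reltol = ctrl$reltol))
  theta_hat <- opt$par
  loglik <- -opt$value

  grad <- pracma::grad(negll, theta_hat)
  grad_norm <- max(abs(grad))
  converged <- opt$convergence == 0 &&
    grad_norm < ctrl$grad_tol * (1 + abs(loglik))

  H <- pracma::hessian(negll, theta_hat)
  H <- (H + t(H)) / 2
  cov <- tryCatch(chol2inv(chol(H)), error = function(e) NULL)
  if (is.null(cov)) {
    warning(warningCondition(
      "observed information is singular; covariance unavailable",
      class = "ltc_singular_information_warning"))
  } else {
    dimnames(cov) <- list(skel$names, skel$names)
  }

  if (!converged)
    warning(warningCondition(
      sprintf("fit did not converge (optim code %d, max |gradient| %.3g)",
              opt$convergence, grad_norm),
      class = "ltc_convergence_warning"))

  structure(list(theta = theta_hat, cov = cov, loglik = loglik,
                 converged = converged, niter = unname(opt$counts[1L]),
                 grad_norm = grad_norm,
                 n_subjects = n_subjects(data), n_obs = nrow(data),
                 structure = structure, formulas = formulas,
                 skeleton = skel),
            class = "ltc_fit")
}

#' Fitted intensity parameters of a model
#'
#' @param fit An `ltc_fit`.
#' @return The point estimates as an [ltc_params()] object.
#' @export
fitted_params <- function(fit) {
  stopifnot(inherits(fit, "ltc_fit"))
  theta_unpack(fit$theta, fit$skeleton)
}

#' @export
coef.ltc_fit <- function(object, ...) object$theta

#' @export
vcov.ltc_fit <- function(object, ...) object$cov

#' @export
logLik.ltc_fit <- function(object, ...) {
  structure(object$loglik, df = length(object$theta), class = "logLik")
}

#' @export
print.ltc_fit <- function(x, ...) {
  cat(sprintf(paste0("Continuous-time multi-state model fit: %d subjects,",
                     " %d observations\n"), x$n_subjects, x$n_obs))
  cat(sprintf("  log-likelihood %.3f, %s (%d evaluations, max|grad| %.2g)\n",
              x$loglik, if (x$converged) "converged" else "NOT converged",
              x$niter, x$grad_norm))
  est <- x$theta
  se <- if (!is.null(x$cov)) sqrt(diag(x$cov)) else rep(NA_real_,
                                                        length(est))
  print(data.frame(estimate = round(est, 4), se = round(se, 4)))
  invisible(x)
}

ci_z <- function(conf_level) {
  # conventional 1.96 for the default 95% level, exact quantile otherwise
  if (abs(conf_level - 0.95) < 1e-12) 1.96
  else stats::qnorm(1 - (1 - conf_level) / 2)
}

#' Hazard ratios for covariate effects on transition intensities
#'
#' The hazard ratio of a covariate on transition i>j is `exp(beta_ij)`,
#' the multiplicative effect of a one-unit covariate increase on that
#' transition's intensity, with Wald interval
#' `exp(beta +/- z * SE(beta))`.
#'
#' @param fit An `ltc_fit`.
#' @param transitions Transition keys to report (default: all with
#'   covariates).
#' @param covariates Covariate names to report (default: all).
#' @param conf_level Confidence level (default 0.95, using z = 1.96).
#' @return data.frame with columns `transition`, `covariate`, `hr`,
#'   `lower`, `upper`, `se_log`.
#' @export
hazard_ratios <- function(fit, transitions = NULL, covariates = NULL,
                          conf_level = 0.95) {
  stopifnot(inherits(fit, "ltc_fit"))
  keys <- names(fit$formulas)[lengths(fit$formulas) > 0L]
  if (!is.null(transitions)) {
    unknown <- setdiff(transitions, keys)
    if (length(unknown))
      stop("transition(s) without covariates or not in model: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    keys <- intersect(keys, transitions)
  }
  z <- ci_z(conf_level)
  se_all <- stats::setNames(
    if (!is.null(fit$cov)) sqrt(pmax(diag(fit$cov), 0))
    else rep(NA_real_, length(fit$theta)),
    names(fit$theta))
  rows <- list()
  for (key in keys) {
    covs <- fit$formulas[[key]]
    if (!is.null(covariates)) {
      unknown <- setdiff(covariates, covs)
      if (length(unknown) && length(keys) == 1L)
        stop("covariate(s) not in formula of ", key, ": ",
             paste(unknown, collapse = ", "), call. = FALSE)
      covs <- intersect(covs, covariates)
    }
    for (cv in covs) {
      nm <- paste0("beta(", key, "):", cv)
      b <- fit$theta[[nm]]
      s <- se_all[[nm]]
      rows[[length(rows) + 1L]] <-
        data.frame(transition = key, covariate = cv, hr = exp(b),
                   lower = exp(b - z * s), upper = exp(b + z * s),
                   se_log = s)
    }
  }
  if (!length(rows))
    stop("no matching covariate effects in the fitted model", call. = FALSE)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Delta-method confidence interval for a function of the parameters
#'
#' Propagates the estimated covariance of the parameter vector through a
#' differentiable scalar function g by the first-order delta method:
#' `SE = sqrt(grad(g)' Cov grad(g))` with the gradient obtained by central
#' finite differences. For strictly positive quantities the interval can
#' be formed on the log scale and back-transformed, and for probabilities
#' on the logit scale, so the interval respects the range constraint.
#'
#' @param fit An `ltc_fit` with available covariance.
#' @param g Function of the full parameter vector theta returning a scalar.
#' @param transform `"identity"`, `"log"` (positive quantities) or
#'   `"logit"` (probabilities).
#' @param conf_level Confidence level (default 0.95, z = 1.96).
#' @return List with `estimate`, `se`, `lower`, `upper`.
#' @export
delta_method_ci <- function(fit, g,
                            transform = c("identity", "log", "logit"),
                            conf_level = 0.95) {
  stopifnot(inherits(fit, "ltc_fit"), is.function(g))
  transform <- match.arg(transform)
  if (is.null(fit$cov))
    stop("covariance unavailable for this fit", call. = FALSE)
  est <- as.numeric(g(fit$theta))
  if (length(est) != 1L || !is.finite(est))
    stop("g(theta) must return a finite scalar", call. = FALSE)
  gr <- pracma::grad(g, fit$theta)
  if (any(!is.finite(gr)))
    stop(errorCondition("non-finite gradient of g",
                        class = c("ltc_numeric_error", "error")))
  se <- sqrt(max(0, as.numeric(t(gr) %*% fit$cov %*% gr)))
  z <- ci_z(conf_level)
  ci <- switch(transform,
    identity = est + c(-1, 1) * z * se,
    log = {
      if (est <= 0) stop("log transform needs a positive estimate",
                         call. = FALSE)
      exp(log(est) + c(-1, 1) * z * se / est)
    },
    logit = {
      if (est <= 0 || est >= 1)
        stop("logit transform needs an estimate in (0, 1)", call. = FALSE)
      stats::plogis(stats::qlogis(est) +
                      c(-1, 1) * z * se / (est * (1 - est)))
    })
  list(estimate = est, se = se, lower = ci[1L], upper = ci[2L])
}
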