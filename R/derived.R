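# Reference covariate profile: every model covariate at 0, overridden by
# any values the caller supplies (extra names are ignored).
full_profile <- function(params, profile = NULL) {
  covs <- params_covariates(params)
  if (!length(covs)) return(NULL)
  z <- stats::setNames(rep(0, length(covs)), covs)
  if (!is.null(profile)) {
    keep <- intersect(names(profile), covs)
    z[keep] <- profile[keep]
  }
  z
}

# Resolve "Q or fit(+profile)" arguments used by the derived summaries.
as_generator <- function(object, profile = NULL) {
  if (inherits(object, "ltc_fit")) {
    p <- fitted_params(object)
    build_generator(p, full_profile(p, profile))
  } else if (inherits(object, "ltc_params")) {
    build_generator(object, full_profile(object, profile))
  } else if (is.matrix(object)) object
  else stop("expected a generator matrix, ltc_params or ltc_fit",
            call. = FALSE)
}

parse_transition_pair <- function(x, Q) {
  if (is.character(x) && length(x) == 1L && grepl(">", x, fixed = TRUE))
    x <- strsplit(x, ">", fixed = TRUE)[[1L]]
  if (length(x) != 2L)
    stop("transition must be 'from>to' or a (from, to) pair", call. = FALSE)
  c(resolve_state(trimws(x[1L]), Q), resolve_state(trimws(x[2L]), Q))
}

#' Transition rate ratio between two transitions
#'
#' The transition rate ratio (TRR) compares the instantaneous propensity
#' of two moves: `q_num / q_den` evaluated at a covariate profile. When a
#' fitted model is supplied, a 95% interval is obtained by the delta
#' method on the log scale (the ratio is positive by construction).
#'
#' @param object Generator matrix, [ltc_params()] or `ltc_fit`.
#' @param numerator,denominator Transitions, `"1>2"` style or (from, to)
#'   pairs.
#' @param profile Named covariate vector at which to evaluate (fit/params
#'   input); default the reference profile (all covariates 0).
#' @param conf_level Confidence level for the fit-based interval.
#' @return List with `value` and, for a fit, `lower`/`upper`/`se`.
#'
#' @examples
#' Q <- matrix(0, 4, 4); Q[1, 2] <- 1; Q[1, 3] <- 1 / 11.08
#' Q[1, 4] <- 1 / 7.72; diag(Q) <- -rowSums(Q)
#' transition_rate_ratio(Q, "1>2", "1>3")$value
#' @export
transition_rate_ratio <- function(object, numerator, denominator,
                                  profile = NULL, conf_level = 0.95) {
  Q <- as_generator(object, profile)
  num <- parse_transition_pair(numerator, Q)
  den <- parse_transition_pair(denominator, Q)
  qd <- Q[den[1L], den[2L]]
  if (qd <= 0)
    stop(errorCondition("denominator transition rate is zero",
                        class = c("ltc_domain_error", "error")))
  value <- Q[num[1L], num[2L]] / qd
  out <- list(value = value)
  if (inherits(object, "ltc_fit") && !is.null(object$cov)) {
    prof <- full_profile(fitted_params(object), profile)
    g <- function(theta) {
      Qt <- build_generator(theta_unpack(theta, object$skeleton), prof)
      Qt[num[1L], num[2L]] / Qt[den[1L], den[2L]]
    }
    ci <- delta_method_ci(object, g, transform = "log",
                          conf_level = conf_level)
    out <- list(value = value, se = ci$se, lower = ci$lower,
                upper = ci$upper)
  }
  out
}

#' Probability distribution of the next state
#'
#' Given current occupation of a transient state, the next state entered
#' is j with probability `q_ij / sum_k q_ik` over the competing exits —
#' the embedded jump-chain probabilities.
#'
#' @param object Generator matrix, [ltc_params()] or `ltc_fit`.
#' @param from_state State label or index; must not be absorbing.
#' @param profile Covariate profile for fit/params input.
#' @return Named numeric vector of probabilities over the possible
#'   successor states, summing to 1.
#'
#' @examples
#' Q <- matrix(0, 4, 4); Q[1, 2] <- 1; Q[1, 3] <- 1 / 11.08
#' Q[1, 4] <- 1 / 7.72; diag(Q) <- -rowSums(Q)
#' round(next_state_probabilities(Q, 1), 2)
#' @export
next_state_probabilities <- function(object, from_state, profile = NULL) {
  Q <- as_generator(object, profile)
  from <- resolve_state(from_state, Q)
  rates <- Q[from, ]
  rates[from] <- 0
  succ <- which(rates > 0)
  if (!length(succ))
    stop(errorCondition(
      paste0("state ", rownames(Q)[from] %||% from,
             " is absorbing: no next state"),
      class = c("ltc_domain_error", "error")))
  p <- rates[succ] / sum(rates[succ])
  names(p) <- (rownames(Q) %||% as.character(seq_len(nrow(Q))))[succ]
  p
}

#' Mean sojourn time in a transient state
#'
#' The expected duration of a single stay in state i is the mean of the
#' exponential holding time, `1 / (-Q[i, i])`.
#'
#' @inheritParams next_state_probabilities
#' @param state State label or index; must not be absorbing.
#' @return Duration in years.
#' @export
mean_sojourn_time <- function(object, state, profile = NULL) {
  Q <- as_generator(object, profile)
  i <- resolve_state(state, Q)
  rate <- -Q[i, i]
  if (rate <= 0)
    stop(errorCondition(
      paste0("state ", rownames(Q)[i] %||% i,
             " is absorbing: sojourn time undefined"),
      class = c("ltc_domain_error", "error")))
  1 / rate
}

#' Expected total length of stay in a state over a horizon
#'
#' The expected cumulative time spent in `target_state` over `[0, T]`
#' starting from `start_state`, `integral_0^T P[start, target](t) dt`,
#' computed by adaptive quadrature for finite T and in closed form via the
#' fundamental matrix of the transient class for `T = Inf` (progressive
#' structures). This is the alternative reading of a reported "average
#' length of stay"; [mean_sojourn_time()] is the primary one.
#'
#' @inheritParams next_state_probabilities
#' @param start_state,target_state State labels or indices.
#' @param horizon Positive duration in years, or `Inf`.
#' @return Duration in years.
#' @export
total_length_of_stay <- function(object, start_state, target_state,
                                 horizon = Inf, profile = NULL) {
  Q <- as_generator(object, profile)
  start <- resolve_state(start_state, Q)
  target <- resolve_state(target_state, Q)
  if (!is.numeric(horizon) || length(horizon) != 1L || horizon <= 0)
    stop(errorCondition("horizon must be > 0 (possibly Inf)",
                        class = c("ltc_domain_error", "error")))
  if (is.infinite(horizon)) {
    transient <- which(diag(Q) < 0)
    if (!target %in% transient)
      stop(errorCondition(
        "total length of stay diverges: target state is absorbing and the horizon infinite",
        class = c("ltc_domain_error", "error")))
    if (!start %in% transient) return(0)
    N <- solve(-Q[transient, transient, drop = FALSE])
    return(N[match(start, transient), match(target, transient)])
  }
  fac <- tpm_factory(Q)
  stats::integrate(function(t) fac$entry(start, target, t),
                   lower = 0, upper = horizon,
                   rel.tol = 1e-10, abs.tol = 1e-12,
                   subdivisions = 500L)$value
}

#' Probability of being alive at time t
#'
#' One minus the probability of having been absorbed into the death state
#' by time t, starting from a given state: `1 - P[from, death](t)`.
#'
#' @inheritParams next_state_probabilities
#' @param t Vector of non-negative times in years.
#' @param death_state Death state label or index; defaults to the single
#'   zero-row (absorbing) state of Q.
#' @return Numeric vector of survival probabilities, one per `t`.
#' @export
survival_probability <- function(object, from_state, t, death_state = NULL,
                                 profile = NULL) {
  Q <- as_generator(object, profile)
  if (any(!is.finite(t)) || any(t < 0))
    stop(errorCondition("t must be >= 0",
                        class = c("ltc_domain_error", "error")))
  from <- resolve_state(from_state, Q)
  if (is.null(death_state)) {
    abs_states <- which(rowSums(Q != 0) == 0L)
    if (length(abs_states) != 1L)
      stop("cannot infer the death state; supply `death_state`",
           call. = FALSE)
    death <- abs_states
  } else death <- resolve_state(death_state, Q)
  fac <- tpm_factory(Q)
  1 - fac$entry(from, death, t)
}

#' Multi-state frequency table of observed trajectories
#'
#' Counts, for every ordered state pair (i, j), the number of subjects
#' whose trajectory left state i next entering state j by the end of
#' follow-up. The diagonal counts subjects remaining in state i at their
#' last observation (for the death state: all deceased). Row sums
#' therefore equal the number of subjects who ever entered state i.
#'
#' @param data An [ltc_panel()].
#' @return Square integer matrix with state dimnames and attribute
#'   `"ever"` (row totals, subjects ever in each state).
#' @export
multistate_frequency_table <- function(data) {
  stopifnot(inherits(data, "ltc_panel"))
  s <- attr(data, "structure")
  n <- length(s$states)
  tab <- matrix(0L, n, n, dimnames = list(s$states, s$states))
  sid <- data$subject_id
  st <- data$state_idx
  first <- which(!duplicated(sid))
  last <- c(first[-1L] - 1L, length(sid))
  for (k in seq_along(first)) {
    seq_k <- st[first[k]:last[k]]
    seq_k <- seq_k[c(TRUE, diff(seq_k) != 0L)]  # collapse repeats
    m <- length(seq_k)
    if (m > 1L)
      for (j in seq_len(m - 1L))
        tab[seq_k[j], seq_k[j + 1L]] <- tab[seq_k[j], seq_k[j + 1L]] + 1L
    tab[seq_k[m], seq_k[m]] <- tab[seq_k[m], seq_k[m]] + 1L
  }
  attr(tab, "ever") <- rowSums(tab)
  tab
}

#' Observed versus expected state prevalence (goodness of fit)
#'
#' Compares, on a grid of times, the observed number of subjects in each
#' state (last observation carried forward between observation times)
#' with the count expected under the model: the sum over subjects of that
#' subject's transition probabilities `P[s0, .](t)` from their baseline
#' state. Close agreement supports the fitted model's description of the
#' cohort's flow through the states.
#'
#' @param object [ltc_params()] or `ltc_fit` supplying the model.
#' @param data An [ltc_panel()].
#' @param times Non-negative grid of times in years.
#' @return Object of class `ltc_prevalence`: a data.frame with columns
#'   `time`, `state`, `observed`, `expected`, and attribute `"n"` (cohort
#'   size). At each time the observed counts sum to n exactly and the
#'   expected counts to n up to roundoff.
#' @export
prevalence_gof <- function(object, data, times) {
  stopifnot(inherits(data, "ltc_panel"))
  if (any(!is.finite(times)) || any(times < 0))
    stop(errorCondition("grid times must be >= 0",
                        class = c("ltc_domain_error", "error")))
  params <- if (inherits(object, "ltc_fit")) fitted_params(object)
            else if (inherits(object, "ltc_params")) object
            else stop("expected ltc_params or ltc_fit", call. = FALSE)
  s <- attr(data, "structure")
  n_states <- length(s$states)
  times <- sort(unique(times))

  # observed: LOCF state per subject at each grid time
  sid <- data$subject_id
  first <- which(!duplicated(sid))
  last <- c(first[-1L] - 1L, length(sid))
  n <- length(first)
  obs <- matrix(0, length(times), n_states)
  for (k in seq_len(n)) {
    tt <- data$time[first[k]:last[k]]
    st <- data$state_idx[first[k]:last[k]]
    pos <- findInterval(times, tt)
    pos[pos < 1L] <- 1L  # grid times before baseline cannot occur (>= 0)
    occ <- st[pos]
    obs[cbind(seq_along(times), occ)] <-
      obs[cbind(seq_along(times), occ)] + 1
  }

  # expected: sum over covariate patterns of pattern size * P[s0, .](t)
  pats <- interval_patterns(data, params)
  bc_first <- first
  pat_subj <- if (length(pats$Z) == 1L && is.null(pats$Z[[1L]]))
    rep(1L, n) else {
    covs <- params_covariates(params)
    bc <- baseline_covariates(data, covs)
    key <- do.call(paste, c(bc[covs], list(sep = "\r")))
    match(key, unique(key))
  }
  s0 <- data$state_idx[bc_first]
  exp_counts <- matrix(0, length(times), n_states)
  for (p in seq_along(pats$Z)) {
    members <- which(pat_subj == p)
    if (!length(members)) next
    Q <- build_generator(params, pats$Z[[p]])
    fac <- tpm_factory(Q)
    for (start in unique(s0[members])) {
      w <- sum(s0[members] == start)
      for (ti in seq_along(times)) {
        exp_counts[ti, ] <- exp_counts[ti, ] +
          w * fac$pmat(times[ti])[start, ]
      }
    }
  }

  out <- data.frame(
    time = rep(times, each = n_states),
    state = rep(s$states, times = length(times)),
    observed = as.vector(t(obs)),
    expected = as.vector(t(exp_counts)))
  attr(out, "n") <- n
  class(out) <- c("ltc_prevalence", "data.frame")
  out
}

#' @export
print.ltc_prevalence <- function(x, ...) {
  n <- attr(x, "n")
  cat(sprintf("Observed vs expected prevalence, cohort n = %d\n", n))
  dev <- max(abs(x$observed - x$expected)) / n
  cat(sprintf("  max normalized discrepancy: %.4f\n", dev))
  NextMethod()
}

#' Model summary in the style of a transition-rate report
#'
#' Assembles, at a covariate profile, the headline derived quantities of a
#' fitted model (or plain parameter set): transition rate ratios between
#' competing exits from each state and between transitions sharing a
#' destination, the next-state probability distribution from each
#' transient state, and the mean sojourn time of each transient state.
#' With a fitted model, 95% delta-method intervals accompany each value
#' (log scale for ratios and sojourns, logit for probabilities).
#'
#' @param object An `ltc_fit` or [ltc_params()].
#' @param profile Covariate profile (default: reference, all zero).
#' @param conf_level Confidence level.
#' @return data.frame with columns `quantity`, `description`, `value`,
#'   `lower`, `upper`.
#' @export
transition_summary <- function(object, profile = NULL, conf_level = 0.95) {
  params <- if (inherits(object, "ltc_fit")) fitted_params(object) else object
  stopifnot(inherits(params, "ltc_params"))
  s <- params$structure
  profile <- full_profile(params, profile)
  Q <- build_generator(params, profile)
  has_fit <- inherits(object, "ltc_fit") && !is.null(object$cov)
  st <- s$states
  rows <- list()
  add <- function(quantity, description, value, lower = NA_real_,
                  upper = NA_real_)
    rows[[length(rows) + 1L]] <<- data.frame(
      quantity = quantity, description = description, value = value,
      lower = lower, upper = upper)

  delta_for <- function(g, transform) {
    if (!has_fit) return(c(NA_real_, NA_real_))
    ci <- delta_method_ci(object, g, transform = transform,
                          conf_level = conf_level)
    c(ci$lower, ci$upper)
  }
  q_of <- function(theta, from, to) {
    Qt <- build_generator(theta_unpack(theta, object$skeleton), profile)
    Qt[from, to]
  }

  al <- s$allowed
  # rate ratios: competing exits from a common source
  for (i in seq_len(length(st))) {
    outs <- which(al[, 1L] == i)
    if (length(outs) >= 2L)
      for (a in seq_len(length(outs) - 1L))
        for (b in seq((a + 1L), length(outs))) {
          ta <- al[outs[a], 2L]; tb <- al[outs[b], 2L]
          val <- Q[i, ta] / Q[i, tb]
          ci <- delta_for(function(th) q_of(th, i, ta) / q_of(th, i, tb),
                          "log")
          add("TRR", sprintf("%s>%s vs %s>%s", st[i], st[ta], st[i],
                             st[tb]), val, ci[1L], ci[2L])
        }
  }
  # rate ratios: transitions into a common destination
  for (j in seq_len(length(st))) {
    ins <- which(al[, 2L] == j)
    if (length(ins) >= 2L)
      for (a in seq(2L, length(ins)))
        for (b in seq_len(a - 1L)) {
          fa <- al[ins[a], 1L]; fb <- al[ins[b], 1L]
          val <- Q[fa, j] / Q[fb, j]
          ci <- delta_for(function(th) q_of(th, fa, j) / q_of(th, fb, j),
                          "log")
          add("TRR", sprintf("%s>%s vs %s>%s", st[fa], st[j], st[fb],
                             st[j]), val, ci[1L], ci[2L])
        }
  }
  # next-state probabilities and sojourn times
  for (i in setdiff(seq_along(st), s$absorbing)) {
    p <- next_state_probabilities(Q, i)
    for (nm in names(p)) {
      jj <- match(nm, st)
      ci <- delta_for(function(th) {
        Qt <- build_generator(theta_unpack(th, object$skeleton), profile)
        next_state_probabilities(Qt, i)[[nm]]
      }, if (p[[nm]] < 1) "logit" else "identity")
      add("next_state_probability",
          sprintf("from %s to %s", st[i], nm), p[[nm]], ci[1L], ci[2L])
    }
    val <- mean_sojourn_time(Q, i)
    ci <- delta_for(function(th) {
      Qt <- build_generator(theta_unpack(th, object$skeleton), profile)
      mean_sojourn_time(Qt, i)
    }, "log")
    add("sojourn", sprintf("mean sojourn in %s (years)", st[i]), val,
        ci[1L], ci[2L])
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
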