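#' Log-likelihood contribution of one observation interval
#'
#' Computes the log-likelihood contribution of a single interval of length
#' `dt` that starts in `from_state` and ends with an observation of
#' `to_state`, under generator `Q`, for each of the three observation
#' types:
#'
#' * `snapshot`: `log P[from, to](dt)` — the state is known only at the two
#'   endpoints and any path between them is possible.
#' * `exact_transition`: `log(q[from, to]) - q_from * dt`, where `q_from`
#'   is the total exit rate of `from_state` — the subject held `from_state`
#'   for the whole interval and then jumped at its exactly recorded end.
#' * `exact_death`: `log( sum_r P[from, r](dt) * q[r, to] )` over states r
#'   other than the absorbing `to_state` — the death time is exact but the
#'   state occupied immediately beforehand is unknown.
#'
#' @param from_state,to_state State labels or indices (w.r.t. `Q`'s
#'   dimnames).
#' @param dt Interval length in years; must be > 0.
#' @param Q Generator matrix (see [build_generator()]).
#' @param obs_type One of `"snapshot"`, `"exact_transition"`,
#'   `"exact_death"`.
#'
#' @return Scalar log-likelihood contribution; `-Inf` (with a warning) for
#'   an observed move of probability zero.
#' @export
interval_log_likelihood <- function(from_state, to_state, dt, Q,
                                    obs_type = c("snapshot",
                                                 "exact_transition",
                                                 "exact_death")) {
  obs_type <- match.arg(obs_type)
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0)
    stop(errorCondition("dt must be a positive scalar",
                        class = c("ltc_data_error", "error")))
  from <- resolve_state(from_state, Q)
  to <- resolve_state(to_state, Q)

  ll <- switch(obs_type,
    snapshot = {
      p <- transition_probability_matrix(Q, dt)[from, to]
      if (p > 0) log(p) else -Inf
    },
    exact_transition = {
      rate <- Q[from, to]
      if (rate > 0) log(rate) + Q[from, from] * dt else -Inf
    },
    exact_death = {
      P <- transition_probability_matrix(Q, dt)
      alive <- setdiff(seq_len(nrow(Q)), to)
      dens <- sum(P[from, alive] * Q[alive, to])
      if (dens > 0) log(dens) else -Inf
    })
  if (!is.finite(ll))
    warning(warningCondition(
      sprintf("zero-probability %s contribution for move %s -> %s over dt = %g",
              obs_type, rownames(Q)[from] %||% from,
              rownames(Q)[to] %||% to, dt),
      class = "ltc_zero_prob_warning"))
  ll
}

resolve_state <- function(x, Q) {
  if (is.character(x)) {
    idx <- match(x, rownames(Q))
    if (is.na(idx)) {
      num <- suppressWarnings(as.integer(x))
      if (!is.na(num)) idx <- num
    }
  } else idx <- as.integer(x)
  if (is.na(idx) || idx < 1L || idx > nrow(Q))
    stop("unknown state: ", x, call. = FALSE)
  idx
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Log-likelihood of a panel dataset
#'
#' Sums [interval_log_likelihood()] contributions over every consecutive
#' observation pair of every subject, rebuilding the generator per subject
#' from that subject's baseline covariates. Subjects sharing a covariate
#' pattern share a generator, and the Markov (memoryless) property makes
#' the contributions of disjoint intervals independent, so the total
#' factorises over intervals.
#'
#' @param data An [ltc_panel()].
#' @param params An [ltc_params()] whose structure matches the data.
#' @return Scalar log-likelihood (0 for an empty dataset); `-Inf` with a
#'   diagnostic warning naming the offending subjects when any observed
#'   move has probability zero.
#' @export
dataset_log_likelihood <- function(data, params) {
  stopifnot(inherits(data, "ltc_panel"), inherits(params, "ltc_params"))
  iv <- panel_intervals(data)
  if (!length(iv$dt)) return(0)
  pats <- interval_patterns(data, params)
  ll <- ll_compute(iv, pats$pat, pats$Z, params)
  bad <- attr(ll, "bad")
  if (length(bad)) {
    warning(warningCondition(
      paste0("zero-probability contribution(s) for subject(s) ",
             paste(utils::head(unique(iv$subject[bad]), 10L),
                   collapse = ", "),
             " (interval ending at data row(s) ",
             paste(utils::head(iv$row[bad], 10L), collapse = ", "), ")"),
      class = "ltc_zero_prob_warning"))
  }
  as.numeric(ll)
}

# Group intervals by subject covariate pattern. Returns pat (pattern index
# per interval) and Z (list of named covariate vectors, one per pattern).
interval_patterns <- function(data, params, iv = panel_intervals(data)) {
  covs <- params_covariates(params)
  if (!length(covs))
    return(list(pat = rep(1L, length(iv$dt)), Z = list(NULL)))
  bc <- baseline_covariates(data, covs)
  for (v in covs) {
    val <- bc[[v]]
    if (!is.numeric(val)) {
      if (is.logical(val)) bc[[v]] <- as.numeric(val)
      else stop("covariate `", v, "` must be numeric (0/1 indicators or ",
                "continuous)", call. = FALSE)
    }
    if (anyNA(bc[[v]]))
      stop("missing values in covariate `", v, "`", call. = FALSE)
  }
  key <- do.call(paste, c(bc[covs], list(sep = "\r")))
  ukey <- unique(key)
  pat_subj <- match(key, ukey)
  Z <- lapply(match(ukey, key), function(i)
    stats::setNames(as.numeric(bc[i, covs]), covs))
  list(pat = pat_subj[match(iv$subject, bc$subject_id)], Z = Z)
}

# Vectorised likelihood core shared by dataset_log_likelihood and the
# fitting objective. Returns the summed log-likelihood with attribute
# "bad" holding indices of -Inf contributions.
ll_compute <- function(iv, pat, Z, params) {
  total <- 0
  bad <- integer(0)
  ll <- numeric(length(iv$dt))
  for (p in unique(pat)) {
    Q <- build_generator(params, Z[[p]])
    sel <- which(pat == p)
    from <- iv$from[sel]; to <- iv$to[sel]
    dt <- iv$dt[sel]; type <- iv$type[sel]
    fac <- NULL
    vals <- numeric(length(sel))

    iet <- type == "exact_transition"
    if (any(iet)) {
      rate <- Q[cbind(from[iet], to[iet])]
      hold <- Q[cbind(from[iet], from[iet])] * dt[iet]
      vals[iet] <- ifelse(rate > 0, log(rate) + hold, -Inf)
    }

    isn <- type == "snapshot"
    if (any(isn)) {
      fac <- fac %||% tpm_factory(Q)
      wi <- which(isn)
      grp <- paste(from[wi], to[wi])
      for (g in unique(grp)) {
        gi <- wi[grp == g]
        pr <- fac$entry(from[gi[1L]], to[gi[1L]], dt[gi])
        vals[gi] <- ifelse(pr > 0, log(pr), -Inf)
      }
    }

    ied <- type == "exact_death"
    if (any(ied)) {
      fac <- fac %||% tpm_factory(Q)
      for (dstate in unique(to[ied])) {
        qd <- Q[, dstate]
        qd[dstate] <- 0
        for (fstate in unique(from[ied & to == dstate])) {
          gi <- which(ied & to == dstate & from == fstate)
          dens <- fac$rowvec_dot(fstate, dt[gi], qd)
          vals[gi] <- ifelse(dens > 0, log(dens), -Inf)
        }
      }
    }

    ll[sel] <- vals
  }
  bad <- which(!is.finite(ll))
  out <- sum(ll)
  attr(out, "bad") <- bad
  out
}
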