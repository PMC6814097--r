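#' Build a subject-specific generator matrix
#'
#' Assembles the generator (transition intensity) matrix Q for one subject
#' under the proportional-intensity model: for each allowed transition i>j,
#' `Q[i, j] = q0_ij * exp(sum(beta_ij * z))`, with the diagonal set to the
#' negative row sum so each row sums to zero. Rows of absorbing states are
#' identically zero. Off-diagonal entries for disallowed transitions are
#' exactly zero.
#'
#' Linear predictors with absolute value above 30 on the log scale raise a
#' numeric-range error naming the transition rather than silently
#' saturating `exp()`.
#'
#' @param params An [ltc_params()] object.
#' @param z Named numeric vector of covariate values for the subject. May be
#'   `NULL` when no transition has coefficients. Every covariate named in
#'   any coefficient vector must be present.
#' @param structure Optional [ltc_structure()]; defaults to the structure
#'   carried by `params`.
#'
#' @return A square numeric generator matrix (events/year) with state
#'   labels as dimnames.
#'
#' @examples
#' p <- ltc_params(ltc_structure(),
#'                 q0 = c("1>2" = 0.10312, "1>3" = 0.00931, "1>4" = 0.01336,
#'                        "2>3" = 0.125, "2>4" = 0.07341, "3>4" = 0.39841))
#' Q <- build_generator(p)
#' rowSums(Q)
#' @export
build_generator <- function(params, z = NULL, structure = params$structure) {
  stopifnot(inherits(params, "ltc_params"))
  n <- length(structure$states)
  Q <- matrix(0, n, n, dimnames = list(structure$states, structure$states))
  al <- structure$allowed
  for (k in seq_along(structure$keys)) {
    key <- structure$keys[k]
    eta <- params$log_q0[[key]]
    b <- params$beta[[key]]
    if (length(b)) {
      missing <- setdiff(names(b), names(z))
      if (length(missing))
        stop(errorCondition(
          paste0("covariate(s) missing from z for transition ", key, ": ",
                 paste(missing, collapse = ", ")),
          class = c("ltc_covariate_error", "error")))
      eta <- eta + sum(b * z[names(b)])
    }
    if (!is.finite(eta) || abs(eta) > 30)
      stop(errorCondition(
        paste0("linear predictor out of numeric range (|eta| > 30) for ",
               "transition ", key, ": eta = ", format(eta)),
        class = c("ltc_numeric_error", "error")))
    Q[al[k, 1L], al[k, 2L]] <- exp(eta)
  }
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  Q
}

#' Validate generator-matrix invariants
#'
#' Checks non-negative off-diagonals, zero row sums (within 1e-12 relative)
#' and, when a structure is supplied, exact zeros on disallowed transitions
#' and all-zero rows for absorbing states.
#'
#' @param Q Square numeric matrix.
#' @param structure Optional [ltc_structure()].
#' @return `TRUE` invisibly; errors describe the first violation.
#' @export
validate_generator <- function(Q, structure = NULL) {
  if (!is.matrix(Q) || nrow(Q) != ncol(Q) || !is.numeric(Q))
    stop("Q must be a square numeric matrix", call. = FALSE)
  off <- Q; diag(off) <- 0
  if (any(off < 0))
    stop("negative off-diagonal intensity in Q", call. = FALSE)
  scale <- max(1, max(abs(Q)))
  if (any(abs(rowSums(Q)) > 1e-12 * scale))
    stop("rows of Q must sum to zero", call. = FALSE)
  if (!is.null(structure)) {
    n <- length(structure$states)
    stopifnot(nrow(Q) == n)
    allowed <- matrix(FALSE, n, n)
    allowed[structure$allowed] <- TRUE
    if (any(off[!allowed & row(Q) != col(Q)] != 0))
      stop("nonzero intensity on a disallowed transition", call. = FALSE)
    if (any(Q[structure$absorbing, ] != 0))
      stop("absorbing-state row of Q must be zero", call. = FALSE)
  }
  invisible(TRUE)
}

#' Transition probability matrix P(t) = exp(tQ)
#'
#' Computes the matrix exponential of `t * Q` by scaling and squaring,
#' giving the probability of being in state j at time t given state i at
#' time 0 under the time-homogeneous Markov chain with generator Q.
#'
#' @param Q Generator matrix (see [build_generator()]).
#' @param t Non-negative duration in years (scalar).
#' @return Stochastic matrix: entries in \[0, 1\], rows summing to 1; equals
#'   the identity at `t = 0`; rows of absorbing states are unit vectors.
#'
#' @examples
#' p <- ltc_params(ltc_structure(),
#'                 q0 = c("1>2" = 0.10312, "1>3" = 0.00931, "1>4" = 0.01336,
#'                        "2>3" = 0.125, "2>4" = 0.07341, "3>4" = 0.39841))
#' P10 <- transition_probability_matrix(build_generator(p), 10)
#' P10["Non-user", ]
#' @export
transition_probability_matrix <- function(Q, t) {
  if (!is.numeric(t) || length(t) != 1L || !is.finite(t) || t < 0)
    stop(errorCondition("t must be a finite scalar >= 0",
                        class = c("ltc_domain_error", "error")))
  P <- expm_ss(Q * t)
  P <- pmin(pmax(P, 0), 1)
  dimnames(P) <- dimnames(Q)
  P
}

#' Chapman-Kolmogorov (semigroup) deviation
#'
#' Validation utility for the Markov property: returns the largest absolute
#' entrywise deviation between `P(s + t)` and `P(s) %*% P(t)`, which is zero
#' (up to roundoff) for any valid generator.
#'
#' @param Q Generator matrix.
#' @param s,t Non-negative durations in years.
#' @return Non-negative scalar deviation.
#' @export
chapman_kolmogorov_check <- function(Q, s, t) {
  Pst <- transition_probability_matrix(Q, s + t)
  Ps <- transition_probability_matrix(Q, s)
  Pt <- transition_probability_matrix(Q, t)
  max(abs(Pst - Ps %*% Pt))
}
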