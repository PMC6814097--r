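# Shared builders for the test suite. Everything is generated in code;
# no stored fixtures.

# Calibrated default parameter set (reference-profile intensities)
default_params <- function() default_true_model()$params

default_Q <- function() build_generator(default_params())

# A two-state alive/dead chain with a single exit rate
two_state_Q <- function(rate) {
  Q <- matrix(c(-rate, rate, 0, 0), 2, 2, byrow = TRUE,
              dimnames = list(c("Alive", "Dead"), c("Alive", "Dead")))
  Q
}

# Random progressive upper-triangular 4-state generator
random_progressive_Q <- function() {
  Q <- matrix(0, 4, 4)
  for (i in 1:3)
    for (j in (i + 1):4)
      Q[i, j] <- stats::runif(1, 0.01, 0.8)
  diag(Q) <- -rowSums(Q)
  Q
}

# Small panel built by hand: subject trajectories given as lists of
# (time, state, obs_type) triples
make_panel <- function(subjects, structure = ltc_structure(), covs = NULL) {
  rows <- list()
  for (id in names(subjects)) {
    tr <- subjects[[id]]
    df <- data.frame(subject_id = id,
                     time = vapply(tr, function(r) as.numeric(r[[1]]), 0),
                     state = vapply(tr, function(r) as.character(r[[2]]),
                                    ""),
                     obs_type = vapply(tr, function(r) as.character(r[[3]]),
                                       ""))
    if (!is.null(covs)) df <- cbind(df, covs[id, , drop = FALSE])
    rows[[id]] <- df
  }
  ltc_panel(do.call(rbind, rows), structure)
}

# Quick simulated panel under the calibrated defaults
quick_panel <- function(n = 300, seed = 42, effects = "none",
                        scheme = "exact") {
  m <- default_true_model(effects = effects)
  observe_cohort(simulate_cohort(m, n = n, seed = seed), scheme)
}

# Forward-equation oracle: integrate dP/dt = P Q row by row with deSolve
ode_tpm <- function(Q, t) {
  n <- nrow(Q)
  deriv <- function(tt, y, parms) list(as.vector(matrix(y, n, n) %*% Q))
  y0 <- as.vector(diag(n))
  sol <- deSolve::lsoda(y0, c(0, t), deriv, parms = NULL,
                        rtol = 1e-11, atol = 1e-12)
  matrix(sol[2, -1], n, n)
}
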