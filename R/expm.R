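# Matrix exponential by scaling and squaring with a degree-13 Pade
# approximant (Higham 2005). Operates on plain base matrices so the
# likelihood inner loop carries no class-dispatch overhead; robust to the
# near-repeated eigenvalues that defeat eigendecomposition.
expm_ss <- function(A) {
  d <- nrow(A)
  if (d != ncol(A)) stop("matrix must be square", call. = FALSE)
  b <- c(64764752532480000, 32382376266240000, 7771770303897600,
         1187353796428800, 129060195264000, 10559470521600,
         670442572800, 33522128640, 1323241920, 40840800, 960960,
         16380, 182, 1)
  theta13 <- 5.371920351148152
  nrmA <- max(colSums(abs(A)))
  if (nrmA == 0) return(diag(d))  # exp(0) = I exactly
  s <- 0L
  if (is.finite(nrmA) && nrmA > theta13)
    s <- as.integer(ceiling(log2(nrmA / theta13)))
  if (!is.finite(nrmA)) stop("non-finite entries in matrix", call. = FALSE)
  As <- A / 2^s
  A2 <- As %*% As
  A4 <- A2 %*% A2
  A6 <- A2 %*% A4
  I <- diag(d)
  U <- As %*% (A6 %*% (b[14] * A6 + b[12] * A4 + b[10] * A2) +
                 b[8] * A6 + b[6] * A4 + b[4] * A2 + b[2] * I)
  V <- A6 %*% (b[13] * A6 + b[11] * A4 + b[9] * A2) +
    b[7] * A6 + b[5] * A4 + b[3] * A2 + b[1] * I
  P <- solve(V - U, V + U)
  for (k in seq_len(s)) P <- P %*% P
  P
}

# Factory for repeated evaluation of entries of P(t) = exp(tQ) at many t
# under one generator Q. Uses the eigendecomposition P(t) = V e^{Lt} V^{-1}
# (vectorised over t) when Q is diagonalisable and well conditioned, else
# falls back to per-t scaling-and-squaring.
tpm_factory <- function(Q) {
  d <- nrow(Q)
  ok <- FALSE
  V <- NULL; Vinv <- NULL; lam <- NULL
  e <- tryCatch(eigen(Q), error = function(err) NULL)
  if (!is.null(e)) {
    V <- e$vectors; lam <- e$values
    Vinv <- tryCatch(solve(V), error = function(err) NULL)
    if (!is.null(Vinv)) {
      recon <- V %*% (lam * Vinv)
      ok <- max(Mod(recon - Q)) < 1e-9 * max(1, max(abs(Q)))
    }
  }

  # P[from, to](t) for a vector of times t (scalar from, to)
  entry <- function(from, to, t) {
    if (ok) {
      coef <- V[from, ] * Vinv[, to]
      val <- Re(exp(outer(t, lam)) %*% coef)[, 1L]
    } else {
      val <- vapply(t, function(tt) expm_ss(Q * tt)[from, to], 0)
    }
    pmin(pmax(val, 0), 1)
  }

  # e_from' exp(Qt) v for a vector of times t (used for exact-death terms)
  rowvec_dot <- function(from, t, v) {
    if (ok) {
      coef <- V[from, ] * as.vector(Vinv %*% v)
      val <- Re(exp(outer(t, lam)) %*% coef)[, 1L]
    } else {
      val <- vapply(t, function(tt) sum(expm_ss(Q * tt)[from, ] * v), 0)
    }
    pmax(val, 0)
  }

  # full matrix P(t), scalar t
  pmat <- function(t) {
    if (ok) {
      P <- Re(V %*% (exp(lam * t) * Vinv))
    } else {
      P <- expm_ss(Q * t)
    }
    pmin(pmax(P, 0), 1)
  }

  list(entry = entry, rowvec_dot = rowvec_dot, pmat = pmat, eigen_ok = ok)
}
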