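#' Intensity parameters of a proportional-intensity Markov model
#'
#' Each allowed transition i>j carries a baseline intensity q0 (events per
#' year, the rate at the covariate reference profile) and, optionally, a
#' vector of log-hazard-ratio coefficients beta, one per covariate in that
#' transition's formula. A subject with covariate vector z experiences the
#' transition at rate `q0 * exp(sum(beta * z))`.
#'
#' @param structure An [ltc_structure()].
#' @param q0 Named numeric vector of baseline intensities (> 0, events per
#'   year). Names are transition keys (`"1>2"` style); every allowed
#'   transition must be present.
#' @param beta Optional named list: one element per transition key holding a
#'   named numeric vector of coefficients (log hazard ratios). Transitions
#'   absent from the list carry no covariate effects.
#'
#' @return An object of class `ltc_params` with elements `structure`,
#'   `log_q0` (named by transition key) and `beta`.
#'
#' @examples
#' s <- ltc_structure()
#' p <- ltc_params(s, q0 = c("1>2" = 0.10312, "1>3" = 0.00931,
#'                           "1>4" = 0.01336, "2>3" = 0.125,
#'                           "2>4" = 0.07341, "3>4" = 0.39841))
#' @export
ltc_params <- function(structure, q0, beta = NULL) {
  stopifnot(inherits(structure, "ltc_structure"))
  if (is.null(names(q0)) || !all(structure$keys %in% names(q0)))
    stop("`q0` must be named and cover every allowed transition: ",
         paste(setdiff(structure$keys, names(q0)), collapse = ", "),
         call. = FALSE)
  extra <- setdiff(names(q0), structure$keys)
  if (length(extra))
    stop("`q0` names not in structure: ", paste(extra, collapse = ", "),
         call. = FALSE)
  q0 <- q0[structure$keys]
  if (any(!is.finite(q0)) || any(q0 <= 0))
    stop("baseline intensities must be finite and > 0", call. = FALSE)

  if (is.null(beta)) beta <- list()
  if (length(beta)) {
    extra <- setdiff(names(beta), structure$keys)
    if (length(extra))
      stop("`beta` names not in structure: ", paste(extra, collapse = ", "),
           call. = FALSE)
    ok <- vapply(beta, function(b)
      is.numeric(b) && (length(b) == 0L || !is.null(names(b))), TRUE)
    if (!all(ok))
      stop("each `beta` element must be a named numeric vector",
           call. = FALSE)
    beta <- beta[lengths(beta) > 0L]
  }

  structure(list(structure = structure,
                 log_q0 = stats::setNames(log(q0), structure$keys),
                 beta = beta),
            class = "ltc_params")
}

#' Covariate names used anywhere in a parameter set
#' @keywords internal
params_covariates <- function(params) {
  unique(unlist(lapply(params$beta, names), use.names = FALSE))
}

#' @export
print.ltc_params <- function(x, ...) {
  cat("Transition intensity parameters (events/year at reference profile)\n")
  st <- x$structure$states
  al <- x$structure$allowed
  for (k in seq_along(x$log_q0)) {
    key <- names(x$log_q0)[k]
    cat(sprintf("  %-16s q0 = %.5f", sprintf("%s>%s", st[al[k, 1L]],
                                             st[al[k, 2L]]),
                exp(x$log_q0[[k]])))
    b <- x$beta[[key]]
    if (length(b))
      cat("  HR:", paste(sprintf("%s=%.3f", names(b), exp(b)),
                         collapse = ", "))
    cat("\n")
  }
  invisible(x)
}
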