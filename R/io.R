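#' Read a panel dataset from long-format CSV
#'
#' The interchange format is UTF-8 CSV with a header and one observation
#' per row: columns `subject_id`, `time` (years from baseline), `state`
#' (label or 1-based index), `obs_type` (`snapshot`, `exact_transition`,
#' `exact_death`), plus one column per baseline covariate. All validation
#' violations are collected and reported in one pass with row numbers.
#'
#' @param path CSV file path.
#' @param structure An [ltc_structure()] the data must conform to.
#' @return An [ltc_panel()].
#' @export
read_panel_csv <- function(path, structure = ltc_structure()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  ltc_panel(df, structure)
}

#' Write a panel dataset to CSV
#'
#' Inverse of [read_panel_csv()]: writes the observation columns and all
#' covariate columns; a write-then-read round trip reproduces the dataset
#' field for field.
#'
#' @param data An [ltc_panel()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_panel_csv <- function(data, path) {
  stopifnot(inherits(data, "ltc_panel"))
  out <- as.data.frame(data)
  out$state_idx <- NULL
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Save / load a fitted model archive
#'
#' The archive is structured text (YAML): package version, transition
#' structure, per-transition formulas, named point estimates, covariance
#' matrix, log-likelihood and convergence metadata. Everything the
#' derived summaries need, so a fit can be reused without the data.
#'
#' @param fit An `ltc_fit`.
#' @param path Output file path (YAML).
#' @return `write_ltc_model()` returns `path` invisibly;
#'   `read_ltc_model()` returns the restored `ltc_fit`.
#' @export
write_ltc_model <- function(fit, path) {
  stopifnot(inherits(fit, "ltc_fit"))
  obj <- list(
    package = "ltcmarkov",
    version = as.character(utils::packageVersion("ltcmarkov")),
    structure = structure_to_list(fit$structure),
    formulas = fit$formulas[lengths(fit$formulas) > 0L],
    theta = as.list(fit$theta),
    cov = if (!is.null(fit$cov)) apply(fit$cov, 1L, as.list,
                                       simplify = FALSE),
    loglik = fit$loglik,
    converged = fit$converged,
    grad_norm = fit$grad_norm,
    niter = fit$niter,
    n_subjects = fit$n_subjects,
    n_obs = fit$n_obs)
  yaml::write_yaml(obj, path, precision = 17L)
  invisible(path)
}

#' @rdname write_ltc_model
#' @export
read_ltc_model <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  obj <- yaml::read_yaml(path)
  s <- structure_from_list(obj$structure)
  formulas <- stats::setNames(rep(list(character(0)), length(s$keys)),
                              s$keys)
  for (key in names(obj$formulas))
    formulas[[key]] <- as.character(unlist(obj$formulas[[key]]))
  skel <- theta_skeleton(s, formulas)
  theta <- stats::setNames(as.numeric(unlist(obj$theta)), names(obj$theta))
  if (!identical(names(theta), skel$names))
    stop("model archive parameter names do not match its structure",
         call. = FALSE)
  cov <- NULL
  if (!is.null(obj$cov)) {
    cov <- do.call(rbind, lapply(obj$cov, function(r) as.numeric(unlist(r))))
    dimnames(cov) <- list(skel$names, skel$names)
  }
  structure(list(theta = theta, cov = cov, loglik = obj$loglik,
                 converged = isTRUE(obj$converged),
                 niter = obj$niter, grad_norm = obj$grad_norm,
                 n_subjects = obj$n_subjects, n_obs = obj$n_obs,
                 structure = s, formulas = formulas, skeleton = skel),
            class = "ltc_fit")
}

#' Read a run configuration file
#'
#' A single YAML file drives command-line runs: input/output paths, the
#' transition structure (see [structure_to_list()] for the layout), the
#' model preset or explicit per-transition formulas, the covariate
#' dictionary (name to type, `binary` or `numeric`), the evaluation
#' profile, the prediction time grid, horizon and seed. Command-line
#' flags override config fields.
#'
#' @param path YAML config path.
#' @return Named list of settings; `structure` is already converted to an
#'   [ltc_structure()] when present.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$structure))
    cfg$structure <- structure_from_list(cfg$structure)
  if (!is.null(cfg$preset)) {
    ok <- c("main", "health-adjusted", "intercept-only")
    if (!cfg$preset %in% ok)
      stop("config preset must be one of: ", paste(ok, collapse = ", "),
           call. = FALSE)
  }
  cfg
}
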