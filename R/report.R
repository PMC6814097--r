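# Report-shaped outputs: CSV tables mirroring the layout of a published
# multi-state analysis (frequency table; rate ratios / next-state
# probabilities / sojourns; hazard ratios; probability curves;
# observed-vs-expected prevalence).

#' Transition-probability and survival curves on a time grid
#'
#' Evaluates `P[from, to](t)` for every state pair and the survival
#' probability from each transient state on a grid, in long format
#' suitable for plotting.
#'
#' @param object Generator matrix, [ltc_params()] or `ltc_fit`.
#' @param times Non-negative grid of times (years).
#' @param profile Covariate profile for fit/params input.
#' @return data.frame with columns `time`, `from`, `to`, `probability`
#'   plus rows with `to = "alive"` holding survival probabilities.
#' @export
probability_curves <- function(object, times, profile = NULL) {
  Q <- as_generator(object, profile)
  if (any(!is.finite(times)) || any(times < 0))
    stop(errorCondition("grid times must be >= 0",
                        class = c("ltc_domain_error", "error")))
  times <- sort(unique(times))
  n <- nrow(Q)
  labels <- rownames(Q) %||% as.character(seq_len(n))
  fac <- tpm_factory(Q)
  rows <- vector("list", length(times))
  abs_states <- which(rowSums(Q != 0) == 0L)
  for (k in seq_along(times)) {
    P <- fac$pmat(times[k])
    df <- data.frame(time = times[k],
                     from = rep(labels, times = n),
                     to = rep(labels, each = n),
                     probability = as.vector(P))
    if (length(abs_states) == 1L) {
      surv <- data.frame(time = times[k], from = labels, to = "alive",
                         probability = 1 - P[, abs_states])
      df <- rbind(df, surv)
    }
    rows[[k]] <- df
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write the full report bundle
#'
#' Emits the paper-shaped CSV outputs into a directory: `table1.csv`
#' (multi-state frequency table), `table2.csv` (rate ratios, next-state
#' probabilities, sojourns with intervals), `table3.csv` (hazard ratios,
#' when the model has covariates), `curves.csv` (transition probability
#' and survival curves) and `prevalence.csv` (observed vs expected state
#' counts).
#'
#' @param fit An `ltc_fit`.
#' @param data An [ltc_panel()] (for the frequency table and observed
#'   prevalence).
#' @param out_dir Output directory (created if needed).
#' @param times Grid for curves and prevalence; default 0..horizon years.
#' @param profile Covariate profile for the derived summaries.
#' @return Character vector of files written, invisibly.
#' @export
write_report <- function(fit, data, out_dir, times = seq(0, 10, by = 0.5),
                         profile = NULL) {
  stopifnot(inherits(fit, "ltc_fit"), inherits(data, "ltc_panel"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)

  tab1 <- multistate_frequency_table(data)
  f <- file.path(out_dir, "table1.csv")
  utils::write.csv(cbind(state = rownames(tab1), as.data.frame(tab1),
                         ever = attr(tab1, "ever")),
                   f, row.names = FALSE, quote = FALSE)
  files <- c(files, f)

  tab2 <- transition_summary(fit, profile = profile)
  f <- file.path(out_dir, "table2.csv")
  utils::write.csv(tab2, f, row.names = FALSE, quote = FALSE)
  files <- c(files, f)

  if (any(lengths(fit$formulas) > 0L) && !is.null(fit$cov)) {
    f <- file.path(out_dir, "table3.csv")
    utils::write.csv(hazard_ratios(fit), f, row.names = FALSE,
                     quote = FALSE)
    files <- c(files, f)
  }

  f <- file.path(out_dir, "curves.csv")
  utils::write.csv(probability_curves(fit, times, profile = profile), f,
                   row.names = FALSE, quote = FALSE)
  files <- c(files, f)

  prev <- prevalence_gof(fit, data, times)
  f <- file.path(out_dir, "prevalence.csv")
  utils::write.csv(as.data.frame(prev), f, row.names = FALSE,
                   quote = FALSE)
  files <- c(files, f)

  invisible(files)
}

#' Rounded display table in published style
#'
#' Formats a [transition_summary()] with the conventional rounding:
#' probabilities, ratios and years all to 2 decimal places.
#'
#' @param summary Output of [transition_summary()].
#' @return data.frame of character columns ready for printing.
#' @export
format_summary_table <- function(summary) {
  fmt <- function(v) ifelse(is.na(v), "", sprintf("%.2f", v))
  data.frame(quantity = summary$quantity,
             description = summary$description,
             value = fmt(summary$value),
             ci = ifelse(is.na(summary$lower), "",
                         sprintf("(%.2f-%.2f)", summary$lower,
                                 summary$upper)))
}
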