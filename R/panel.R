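#' Construct and validate a panel dataset of state observations
#'
#' A panel dataset holds, per subject, a time-ordered sequence of state
#' observations together with time-fixed baseline covariates, in long
#' format (one row per observation). Three observation types are
#' supported:
#'
#' * `snapshot` — the state at a scheduled observation time; the path in
#'   between is interval-censored.
#' * `exact_transition` — an exactly dated entry into a new state, with the
#'   subject known to have held the previous state throughout the interval
#'   (administrative care-entry records).
#' * `exact_death` — an exactly dated entry into an absorbing state with
#'   the state immediately beforehand unknown (death records).
#'
#' @param data A data.frame with columns `subject_id`, `time` (years from
#'   baseline), `state` (label or index), `obs_type`, plus one column per
#'   baseline covariate.
#' @param structure An [ltc_structure()].
#'
#' @details Validation enforces, reporting all violations at once with row
#' numbers: strictly increasing times within subject (ties are a data
#' error); first observation of every subject at time 0; no observation
#' after one in an absorbing state; observed consecutive state pairs
#' reachable under the structure (for the progressive default, state
#' indices never decrease); `exact_death` only for absorbing states;
#' known observation types and state labels.
#'
#' @return The validated data.frame, ordered by subject then time, with
#'   class `ltc_panel`, integer column `state_idx`, and the structure
#'   attached as attribute `"structure"`.
#' @export
ltc_panel <- function(data, structure = ltc_structure()) {
  stopifnot(inherits(structure, "ltc_structure"))
  required <- c("subject_id", "time", "state", "obs_type")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols))
    stop(errorCondition(
      paste0("missing required column(s): ",
             paste(missing_cols, collapse = ", ")),
      class = c("ltc_validation_error", "error")))

  data <- as.data.frame(data)
  problems <- character()
  note <- function(...) problems <<- c(problems, paste0(...))

  st_idx <- suppressWarnings(match_states_quiet(data$state, structure$states))
  bad <- which(is.na(st_idx))
  if (length(bad))
    note("unknown state label at row(s) ",
         paste(utils::head(bad, 10L), collapse = ", "))

  ok_types <- c("snapshot", "exact_transition", "exact_death")
  bad <- which(!data$obs_type %in% ok_types)
  if (length(bad))
    note("unknown obs_type at row(s) ",
         paste(utils::head(bad, 10L), collapse = ", "))

  if (!is.numeric(data$time) || anyNA(data$time))
    note("`time` must be numeric and non-missing")

  if (!length(problems)) {
    ord <- order(data$subject_id, data$time)
    data <- data[ord, , drop = FALSE]
    st_idx <- st_idx[ord]
    rownames(data) <- NULL
    data$state_idx <- st_idx

    sid <- data$subject_id
    first <- !duplicated(sid)
    bad <- which(first & data$time != 0)
    if (length(bad))
      note("first observation not at time 0 for subject(s) ",
           paste(utils::head(unique(sid[bad]), 10L), collapse = ", "))

    n <- nrow(data)
    if (n > 1L) {
      same <- sid[-1L] == sid[-n]
      dt <- data$time[-1L] - data$time[-n]
      bad <- which(same & dt <= 0)
      if (length(bad))
        note("non-increasing times (ties are a data error) for subject(s) ",
             paste(utils::head(unique(sid[bad + 1L]), 10L), collapse = ", "),
             " at row(s) ", paste(utils::head(bad + 1L, 10L), collapse = ", "))

      absorbing <- st_idx %in% structure$absorbing
      bad <- which(same & absorbing[-n])
      if (length(bad))
        note("observation after an absorbing state for subject(s) ",
             paste(utils::head(unique(sid[bad + 1L]), 10L), collapse = ", "))

      reach <- reachability(structure)
      pair_ok <- reach[cbind(st_idx[-n], st_idx[-1L])]
      bad <- which(same & !pair_ok)
      if (length(bad))
        note("state sequence violates the transition structure for ",
             "subject(s) ",
             paste(utils::head(unique(sid[bad + 1L]), 10L), collapse = ", "),
             " at row(s) ", paste(utils::head(bad + 1L, 10L), collapse = ", "))
    }

    bad <- which(data$obs_type == "exact_death" &
                   !st_idx %in% structure$absorbing)
    if (length(bad))
      note("obs_type 'exact_death' on a non-absorbing state at row(s) ",
           paste(utils::head(bad, 10L), collapse = ", "))
  }

  if (length(problems))
    stop(errorCondition(
      paste0("panel data validation failed:\n  - ",
             paste(problems, collapse = "\n  - ")),
      class = c("ltc_validation_error", "error")))

  data$state <- structure$states[data$state_idx]
  attr(data, "structure") <- structure
  class(data) <- c("ltc_panel", "data.frame")
  data
}

match_states_quiet <- function(x, states) {
  idx <- match(as.character(x), states)
  num <- suppressWarnings(as.integer(as.character(x)))
  fix <- is.na(idx) & !is.na(num) & num >= 1L & num <= length(states)
  idx[fix] <- num[fix]
  idx
}

#' Number of subjects in a panel dataset
#' @param data An [ltc_panel()].
#' @return Integer count of distinct subjects.
#' @export
n_subjects <- function(data) length(unique(data$subject_id))

#' Baseline covariate values, one row per subject
#'
#' Covariates are time-fixed at baseline, so the first row of each subject
#' carries them; this extracts that row for the requested columns.
#'
#' @param data An [ltc_panel()].
#' @param covariates Character vector of covariate column names; default
#'   all columns other than the observation columns.
#' @return data.frame with `subject_id` plus one column per covariate.
#' @export
baseline_covariates <- function(data, covariates = NULL) {
  reserved <- c("subject_id", "time", "state", "obs_type", "state_idx")
  if (is.null(covariates)) covariates <- setdiff(names(data), reserved)
  missing_cols <- setdiff(covariates, names(data))
  if (length(missing_cols))
    stop("covariate column(s) not in data: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  first <- !duplicated(data$subject_id)
  out <- data[first, c("subject_id", covariates), drop = FALSE]
  class(out) <- "data.frame"
  attr(out, "structure") <- NULL
  rownames(out) <- NULL
  out
}

#' @export
`[.ltc_panel` <- function(x, ...) {
  out <- NextMethod()
  if (is.data.frame(out)) {
    attr(out, "structure") <- attr(x, "structure")
    class(out) <- class(x)
  }
  out
}

#' @export
print.ltc_panel <- function(x, ...) {
  s <- attr(x, "structure")
  cat(sprintf("Panel dataset: %d observations on %d subjects, %d states\n",
              nrow(x), n_subjects(x), length(s$states)))
  cat("  obs types:",
      paste(sprintf("%s=%d", names(table(x$obs_type)), table(x$obs_type)),
            collapse = ", "), "\n")
  NextMethod()
}

# Consecutive observation pairs of a panel, as parallel vectors.
# Returns a list with subject, from (state index), to, dt, type (of the
# later observation), and the row index of the later observation.
panel_intervals <- function(data) {
  n <- nrow(data)
  if (n < 2L)
    return(list(subject = character(0), from = integer(0), to = integer(0),
                dt = numeric(0), type = character(0), row = integer(0)))
  sid <- data$subject_id
  same <- sid[-1L] == sid[-n]
  idx <- which(same)
  list(subject = sid[idx + 1L],
       from = data$state_idx[idx],
       to = data$state_idx[idx + 1L],
       dt = data$time[idx + 1L] - data$time[idx],
       type = data$obs_type[idx + 1L],
       row = idx + 1L)
}
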