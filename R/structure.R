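#' Define a multi-state transition structure
#'
#' A transition structure names the states of a continuous-time multi-state
#' model, lists the directed transitions the model permits, and identifies
#' the absorbing states. The default is the four-state aged-care pathway
#' used throughout this package: Non-user (1), home and community care
#' (HACC, 2), residential aged care (RAC, 3) and Death (4), with the six
#' forward transitions 1>2, 1>3, 1>4, 2>3, 2>4 and 3>4 and no reverse
#' movement, so trajectories progress monotonically towards death.
#'
#' @param states Character vector of state labels, in display order. State
#'   indices used elsewhere (transition keys such as `"1>2"`) refer to
#'   positions in this vector.
#' @param transitions Allowed transitions, either a character vector of
#'   `"from>to"` strings (indices or state labels) or a two-column integer
#'   matrix of (from, to) pairs. Defaults to the six progressive aged-care
#'   transitions when `states` has length four.
#' @param absorbing States with no outgoing transitions; indices or labels.
#'   Defaults to the states that have no outgoing allowed transition.
#'
#' @return An object of class `ltc_structure`: a list with elements
#'   `states`, `allowed` (two-column integer matrix), `keys` (transition
#'   keys `"i>j"`) and `absorbing` (integer state indices).
#'
#' @examples
#' str4 <- ltc_structure()
#' str4$keys
#' is_progressive(str4)
#' @export
ltc_structure <- function(states = c("Non-user", "HACC", "RAC", "Death"),
                          transitions = NULL,
                          absorbing = NULL) {
  if (!is.character(states) || length(states) < 2L || anyDuplicated(states))
    stop("`states` must be two or more distinct state labels", call. = FALSE)
  n <- length(states)

  if (is.null(transitions)) {
    if (n != 4L)
      stop("default transitions exist only for the 4-state structure; ",
           "supply `transitions`", call. = FALSE)
    transitions <- c("1>2", "1>3", "1>4", "2>3", "2>4", "3>4")
  }
  allowed <- parse_transitions(transitions, states)
  if (anyDuplicated(paste(allowed[, 1L], allowed[, 2L])))
    stop("duplicate transitions in `transitions`", call. = FALSE)
  if (any(allowed[, 1L] == allowed[, 2L]))
    stop("self-transitions are not allowed", call. = FALSE)

  has_exit <- tabulate(allowed[, 1L], nbins = n) > 0L
  if (is.null(absorbing)) {
    absorbing <- which(!has_exit)
  } else {
    absorbing <- match_states(absorbing, states)
    bad <- absorbing[has_exit[absorbing]]
    if (length(bad))
      stop("absorbing state(s) with outgoing transitions: ",
           paste(states[bad], collapse = ", "), call. = FALSE)
  }

  out <- structure(
    list(states = states,
         allowed = allowed,
         keys = sprintf("%d>%d", allowed[, 1L], allowed[, 2L]),
         absorbing = as.integer(absorbing)),
    class = "ltc_structure")
  out
}

# resolve states given as labels or integer indices to integer indices
match_states <- function(x, states) {
  if (is.numeric(x)) {
    idx <- as.integer(x)
  } else {
    idx <- match(as.character(x), states)
    # allow "3" style numeric strings
    num <- suppressWarnings(as.integer(as.character(x)))
    idx[is.na(idx) & !is.na(num)] <- num[is.na(idx) & !is.na(num)]
  }
  if (anyNA(idx) || any(idx < 1L) || any(idx > length(states)))
    stop("unknown state(s): ",
         paste(x[is.na(idx) | idx < 1L | idx > length(states)],
               collapse = ", "), call. = FALSE)
  idx
}

parse_transitions <- function(transitions, states) {
  if (is.matrix(transitions)) {
    if (ncol(transitions) != 2L)
      stop("transition matrix must have two columns", call. = FALSE)
    from <- match_states(transitions[, 1L], states)
    to <- match_states(transitions[, 2L], states)
  } else if (is.character(transitions)) {
    parts <- strsplit(transitions, ">", fixed = TRUE)
    if (any(lengths(parts) != 2L))
      stop("transitions must be 'from>to' strings", call. = FALSE)
    from <- match_states(trimws(vapply(parts, `[`, "", 1L)), states)
    to <- match_states(trimws(vapply(parts, `[`, "", 2L)), states)
  } else {
    stop("`transitions` must be a character vector or two-column matrix",
         call. = FALSE)
  }
  cbind(from = from, to = to)
}

#' Test whether a structure is progressive (acyclic)
#'
#' A progressive structure admits no directed cycle, so every trajectory
#' moves monotonically towards an absorbing state and no state can be
#' re-entered once left.
#'
#' @param structure An [ltc_structure()].
#' @return `TRUE` if the directed transition graph is acyclic.
#' @export
is_progressive <- function(structure) {
  stopifnot(inherits(structure, "ltc_structure"))
  n <- length(structure$states)
  adj <- matrix(FALSE, n, n)
  adj[structure$allowed] <- TRUE
  # Kahn's algorithm: repeatedly strip sources
  remaining <- rep(TRUE, n)
  repeat {
    indeg <- colSums(adj[remaining, , drop = FALSE])
    src <- remaining & indeg == 0
    if (!any(src)) break
    remaining[src] <- FALSE
  }
  !any(remaining)
}

#' Reachability closure of a structure
#'
#' @param structure An [ltc_structure()].
#' @return Logical matrix; entry (i, j) is `TRUE` when j is reachable from
#'   i through allowed transitions (every state reaches itself).
#' @keywords internal
reachability <- function(structure) {
  n <- length(structure$states)
  reach <- diag(n) > 0
  adj <- matrix(FALSE, n, n)
  adj[structure$allowed] <- TRUE
  for (k in seq_len(n)) reach <- reach | (reach %*% adj) > 0
  reach
}

transition_index <- function(structure, from, to) {
  from <- match_states(from, structure$states)
  to <- match_states(to, structure$states)
  idx <- match(sprintf("%d>%d", from, to), structure$keys)
  if (anyNA(idx))
    stop("transition(s) not in structure: ",
         paste(sprintf("%s>%s", structure$states[from],
                       structure$states[to])[is.na(idx)], collapse = ", "),
         call. = FALSE)
  idx
}

#' @export
print.ltc_structure <- function(x, ...) {
  cat("Multi-state transition structure\n")
  cat("  states:   ", paste(sprintf("%d=%s", seq_along(x$states), x$states),
                            collapse = ", "), "\n")
  cat("  allowed:  ", paste(sprintf("%s>%s", x$states[x$allowed[, 1L]],
                                    x$states[x$allowed[, 2L]]),
                            collapse = ", "), "\n")
  cat("  absorbing:", paste(x$states[x$absorbing], collapse = ", "), "\n")
  cat("  progressive:", is_progressive(x), "\n")
  invisible(x)
}

#' Serialize a structure to / from a plain list
#'
#' The list form is what the YAML run configuration stores: state labels,
#' `"from>to"` transition strings (by label) and absorbing state labels.
#'
#' @param structure An [ltc_structure()].
#' @param x A list with elements `states`, `transitions`, `absorbing`.
#' @return `structure_to_list()` returns the list form;
#'   `structure_from_list()` rebuilds the `ltc_structure`.
#' @export
structure_to_list <- function(structure) {
  stopifnot(inherits(structure, "ltc_structure"))
  list(states = structure$states,
       transitions = sprintf("%s>%s",
                             structure$states[structure$allowed[, 1L]],
                             structure$states[structure$allowed[, 2L]]),
       absorbing = structure$states[structure$absorbing])
}

#' @rdname structure_to_list
#' @export
structure_from_list <- function(x) {
  ltc_structure(states = as.character(x$states),
                transitions = as.character(x$transitions),
                absorbing = if (length(x$absorbing)) x$absorbing)
}
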