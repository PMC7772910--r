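#' Construct a match set
#'
#' The solution container shared by all three solvers: a set of disjoint
#' (user, AED, emergency) triples. A user appears at most once, an AED at
#' most once; an emergency may receive any number of responders. The total
#' match time is the sum of the member travel times.
#'
#' @param matches data frame with columns `user_id`, `aed_id`,
#'   `emergency_id`, `travel_time` (seconds); `NULL` for the empty solution.
#' @param method optional label (`"bm"`, `"ilp"`, `"ppilp"`, ...).
#' @param emergency_ids optional character vector of all emergencies in the
#'   scenario, so per-emergency counts include zero-match emergencies.
#' @param objective optional achieved inverted-time objective value.
#' @param min_pair optional achieved minimum per-emergency count (fairness).
#' @return An object of class `match_set`. Matches are stored sorted
#'   lexicographically by (user, AED, emergency) so identical solutions
#'   serialize identically.
#' @export
new_match_set <- function(matches = NULL, method = NULL, emergency_ids = NULL,
                          objective = NULL, min_pair = NULL) {
  if (is.null(matches) || nrow(as.data.frame(matches)) == 0L) {
    matches <- data.frame(user_id = character(0), aed_id = character(0),
                          emergency_id = character(0),
                          travel_time = numeric(0), stringsAsFactors = FALSE)
  } else {
    matches <- as.data.frame(matches, stringsAsFactors = FALSE)
    need <- c("user_id", "aed_id", "emergency_id", "travel_time")
    stopifnot(all(need %in% names(matches)))
    matches <- matches[, need]
    matches$user_id <- as.character(matches$user_id)
    matches$aed_id <- as.character(matches$aed_id)
    matches$emergency_id <- as.character(matches$emergency_id)
    matches$travel_time <- as.numeric(matches$travel_time)
    ord <- order(matches$user_id, matches$aed_id, matches$emergency_id,
                 method = "radix")
    matches <- matches[ord, , drop = FALSE]
    rownames(matches) <- NULL
  }
  ids <- sort(unique(c(emergency_ids, matches$emergency_id)))
  counts <- stats::setNames(integer(length(ids)), ids)
  if (nrow(matches)) {
    tab <- table(matches$emergency_id)
    counts[names(tab)] <- as.integer(tab)
  }
  structure(
    list(matches = matches,
         total_match_time = sum(matches$travel_time),
         per_emergency_counts = counts,
         method = method, objective = objective, min_pair = min_pair),
    class = "match_set")
}

#' Summarize a match set
#'
#' Totals as reported in the experiment tables of responder-network studies:
#' the match count, the total match time (sum of selected travel times), the
#' per-emergency match counts and the number of unique emergencies covered
#' (emergencies with at least one responder -- the diagnostic that exposes
#' greedy time-only matching).
#'
#' @param match_set a `match_set`.
#' @return A list with elements `n_matches`, `total_match_time`,
#'   `per_emergency_counts`, `unique_emergencies_covered`.
#' @export
match_summary <- function(match_set) {
  stopifnot(inherits(match_set, "match_set"))
  list(n_matches = nrow(match_set$matches),
       total_match_time = match_set$total_match_time,
       per_emergency_counts = match_set$per_emergency_counts,
       unique_emergencies_covered =
         sum(match_set$per_emergency_counts >= 1L))
}

#' @export
print.match_set <- function(x, ...) {
  s <- match_summary(x)
  cat(sprintf("<match_set%s> %d match(es), total match time %.2f s\n",
              if (is.null(x$method)) "" else paste0(": ", x$method),
              s$n_matches, s$total_match_time))
  if (length(s$per_emergency_counts)) {
    cat("  per emergency:",
        paste(sprintf("%s=%d", names(s$per_emergency_counts),
                      s$per_emergency_counts), collapse = ", "),
        sprintf("(%d covered)\n", s$unique_emergencies_covered))
  }
  if (s$n_matches) {
    print(utils::head(x$matches, 10L))
    if (s$n_matches > 10L) cat("  ...", s$n_matches - 10L, "more\n")
  }
  invisible(x)
}

#' @export
summary.match_set <- function(object, ...) {
  s <- match_summary(object)
  print(object)
  invisible(s)
}

# Internal: assert the MatchSet invariants; used by tests on every solver
# output and by save_matches() preconditions.
check_match_set <- function(ms, max_edge_weight = NULL, horizon = NULL) {
  m <- ms$matches
  ok <- !anyDuplicated(m$user_id) && !anyDuplicated(m$aed_id) &&
    all(is.finite(m$travel_time)) && all(m$travel_time >= 0) &&
    isTRUE(all.equal(sum(m$travel_time), ms$total_match_time)) &&
    sum(ms$per_emergency_counts) == nrow(m)
  if (!is.null(max_edge_weight)) ok <- ok && all(m$travel_time < max_edge_weight)
  if (!is.null(horizon)) ok <- ok && all(m$travel_time <= horizon)
  ok
}
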