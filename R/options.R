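#' Solver options
#'
#' Shared configuration for the three matching algorithms.
#'
#' @param method `"ppilp"` (travel-time-sliced exact matching, the default),
#'   `"ilp"` (one-shot exact matching) or `"bm"` (iterative Hungarian
#'   matching over combined AED-emergency columns).
#' @param travel_time_interval band width in seconds for the sliced method
#'   (a typical dispatcher configuration uses 100 s bands). Must satisfy
#'   `0 < travel_time_interval <= horizon`.
#' @param horizon dispatcher cutoff in seconds: no match may require more
#'   travel time than this. Default 1000 s ("notify all users that can reach
#'   the emergency in 1000 s"). Only the sliced method enforces it; set it to
#'   `max(travel_time)` to disable truncation.
#' @param fairness logical; when `TRUE` the solver lexicographically
#'   maximizes the minimum per-emergency match count (max-min fairness)
#'   before optimizing travel time, preventing greedy concentration of all
#'   responders on the nearest emergency.
#' @param cap optional positive integer: at most this many responders per
#'   emergency.
#' @param seed integer seed echoed into reports; the solvers themselves are
#'   deterministic.
#' @return An object of class `solver_options`.
#' @export
solver_options <- function(method = c("ppilp", "ilp", "bm"),
                           travel_time_interval = 100,
                           horizon = 1000,
                           fairness = FALSE,
                           cap = NULL,
                           seed = 1L) {
  method <- match.arg(method)
  stopifnot(is.finite(horizon), travel_time_interval > 0,
            travel_time_interval <= horizon)
  if (!is.null(cap)) {
    cap <- as.integer(cap)
    stopifnot(length(cap) == 1L, cap >= 1L)
  }
  structure(list(method = method,
                 travel_time_interval = as.numeric(travel_time_interval),
                 horizon = as.numeric(horizon),
                 fairness = isTRUE(fairness),
                 cap = cap,
                 seed = as.integer(seed)),
            class = "solver_options")
}
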