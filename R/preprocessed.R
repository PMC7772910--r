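#' Pre-filter paths for one travel-time band
#'
#' The slicing step of the banded solver: retain exactly the
#' battery-feasible paths whose travel time does not exceed the band limit
#' and whose user and AED are both still unmatched. The parent path set's
#' `max_edge_weight` is preserved (not recomputed) so the inverted-time
#' objective uses the same constant in every band.
#'
#' @param path_set a [enumerate_paths()] result.
#' @param iteration_travel_time band limit in seconds (> 0); paths with
#'   `travel_time <= iteration_travel_time` are retained (inclusive).
#' @param matched_users,matched_aeds ids fixed in earlier bands.
#' @return A sliced `path_set`.
#' @export
slice_paths <- function(path_set, iteration_travel_time,
                        matched_users = character(0),
                        matched_aeds = character(0)) {
  stopifnot(inherits(path_set, "path_set"), iteration_travel_time > 0)
  p <- path_set$paths
  keep <- p$battery_feasible &
    p$travel_time <= iteration_travel_time &
    !(p$user_id %in% matched_users) &
    !(p$aed_id %in% matched_aeds)
  new_path_set(p[keep, , drop = FALSE],
               max_edge_weight = path_set$max_edge_weight,
               n_available = path_set$n_available,
               n_functional = path_set$n_functional,
               n_emergencies = path_set$n_emergencies,
               emergency_ids = path_set$emergency_ids,
               sliced = TRUE)
}

#' Travel-time-sliced exact matching
#'
#' The proposed fast method: instead of solving one matching problem over
#' every candidate path, solve a sequence of small problems over ascending
#' travel-time bands (`interval`, `2*interval`, ... up to `horizon`, the
#' final band clamped to the horizon). Before each band, paths of matched
#' users/AEDs and battery-infeasible paths are filtered out; matches
#' accumulate across bands and the iteration stops early once no unmatched
#' feasible path within the horizon remains. Near responders are thereby
#' dispatched by small, fast solves; with fairness enabled, the max-min
#' objective is evaluated cumulatively over carried plus new matches.
#'
#' @param scenario an [rns_scenario()].
#' @param provider a [distance_provider()].
#' @param options a [solver_options()]; `travel_time_interval`, `horizon`,
#'   `fairness` and `cap` are honored.
#' @return A `match_set` (method `"ppilp"`); every match has
#'   `travel_time <= horizon`.
#' @export
match_preprocessed <- function(scenario,
                               provider = distance_provider("euclidean"),
                               options = solver_options("ppilp")) {
  ps <- enumerate_paths(scenario, provider)
  M <- new_match_set(method = "ppilp", emergency_ids = ps$emergency_ids)
  if (!nrow(ps$paths)) return(M)
  horizon <- options$horizon
  interval <- options$travel_time_interval
  bands <- seq(interval, horizon, by = interval)
  if (!length(bands) || bands[length(bands)] < horizon) {
    bands <- c(bands, horizon)                      # clamp the final band
  }
  feasible_pool <- function(M) {
    p <- ps$paths
    sum(p$battery_feasible & p$travel_time <= horizon &
          !(p$user_id %in% M$matches$user_id) &
          !(p$aed_id %in% M$matches$aed_id))
  }
  for (band in bands) {
    sub <- slice_paths(ps, band,
                       matched_users = M$matches$user_id,
                       matched_aeds = M$matches$aed_id)
    if (nrow(sub$paths)) {
      model <- build_ilp(sub, options, carried = M)
      sol <- solve_ilp(model)
      if (nrow(sol$matches)) {
        M <- new_match_set(rbind(M$matches, sol$matches), method = "ppilp",
                           emergency_ids = ps$emergency_ids)
      }
    }
    if (feasible_pool(M) == 0L) break
  }
  M$objective <- sum(ps$max_edge_weight - M$matches$travel_time)
  M$min_pair <- if (length(ps$emergency_ids)) {
    min(M$per_emergency_counts[ps$emergency_ids])
  } else 0L
  M
}
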