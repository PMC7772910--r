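#' Build the user x (AED, emergency) cost matrix
#'
#' Converts the three-group matching problem into a two-group one by
#' combining AEDs and emergencies into columns, one column per (AED,
#' emergency) pair; cells hold the path travel time in seconds. Cells whose
#' path fails the battery check are set to the sentinel `max_edge_weight`
#' (max travel time + 1), as are whole rows/columns of already-matched users
#' and AEDs; users with no battery-feasible path are dropped entirely. The
#' matrix is padded square with sentinel-filled dummy rows or columns so the
#' Hungarian algorithm applies.
#'
#' @param path_set a [enumerate_paths()] result.
#' @param matched_users,matched_aeds ids already fixed in earlier iterations;
#'   their rows/columns are sentineled out before re-solving.
#' @return A square numeric matrix of class `cost_matrix` with user ids as
#'   row names and `"aedId|emergencyId"` column names (dummies named
#'   `".dummy<k>"`), carrying the sentinel in attribute `max_edge_weight`;
#'   or `NULL` when no user has any battery-feasible path left (the
#'   empty-result signal).
#' @export
build_cost_matrix <- function(path_set, matched_users = character(0),
                              matched_aeds = character(0)) {
  stopifnot(inherits(path_set, "path_set"))
  p <- path_set$paths
  if (!nrow(p)) return(NULL)
  mew <- path_set$max_edge_weight
  users <- sort(unique(p$user_id[p$battery_feasible]))
  users <- setdiff(users, matched_users)
  if (!length(users)) return(NULL)
  aeds <- sort(unique(p$aed_id))
  emergencies <- sort(unique(p$emergency_id))
  cols <- expand.grid(emergency_id = emergencies, aed_id = aeds,
                      stringsAsFactors = FALSE)
  cols <- cols[, c("aed_id", "emergency_id")]
  cols <- cols[order(cols$aed_id, cols$emergency_id, method = "radix"), ]
  col_key <- paste(cols$aed_id, cols$emergency_id, sep = "|")
  mat <- matrix(mew, nrow = length(users), ncol = length(col_key),
                dimnames = list(users, col_key))
  keep <- p$battery_feasible & p$user_id %in% users
  pk <- p[keep, , drop = FALSE]
  mat[cbind(match(pk$user_id, users),
            match(paste(pk$aed_id, pk$emergency_id, sep = "|"), col_key))] <-
    pk$travel_time
  if (length(matched_aeds)) {
    mat[, cols$aed_id %in% matched_aeds] <- mew
  }
  # square off with dummy rows/columns at the sentinel weight
  nr <- nrow(mat); nc <- ncol(mat)
  if (nr < nc) {
    pad <- matrix(mew, nc - nr, nc,
                  dimnames = list(paste0(".dummy", seq_len(nc - nr)), col_key))
    mat <- rbind(mat, pad)
  } else if (nc < nr) {
    pad <- matrix(mew, nr, nr - nc,
                  dimnames = list(rownames(mat),
                                  paste0(".dummy", seq_len(nr - nc))))
    mat <- cbind(mat, pad)
  }
  attr(mat, "max_edge_weight") <- mew
  class(mat) <- c("cost_matrix", class(mat))
  mat
}

#' Solve one square assignment problem
#'
#' Minimum-cost perfect assignment of rows to columns (the Hungarian
#' method). Deterministic: identical matrices yield identical assignments.
#'
#' @param matrix square numeric cost matrix (non-negative).
#' @return Data frame with columns `row`, `col` (indices) and `cost`.
#' @export
hungarian_assign <- function(matrix) {
  stopifnot(is.matrix(matrix), nrow(matrix) == ncol(matrix),
            all(is.finite(matrix)), all(matrix >= 0))
  m <- unclass(matrix)
  attr(m, "max_edge_weight") <- NULL
  sol <- clue::solve_LSAP(m, maximum = FALSE)
  idx <- seq_len(nrow(m))
  data.frame(row = idx, col = as.integer(sol),
             cost = m[cbind(idx, as.integer(sol))])
}

#' Filter one iteration's assignment into accepted matches
#'
#' Post-processing after a Hungarian solve: drops pairs at the sentinel
#' weight (dummy rows/columns and battery-infeasible cells), resolves
#' duplicate AEDs among the iteration's own pairs by keeping the lower
#' travel time, and reconciles with previously selected matches -- on a user
#' or AED conflict the lower-travel-time match wins. Ties break
#' lexicographically by (user, AED, emergency) id.
#'
#' @param assignments data frame from [hungarian_assign()] run on a
#'   [build_cost_matrix()] matrix (the matrix is needed for the dimnames).
#' @param cost_matrix the matrix the assignment was computed on.
#' @param current_matches a `match_set` of matches fixed so far.
#' @param max_edge_weight the sentinel value.
#' @return A list with `match_set` (the merged selection) and `accepted`
#'   (the number of genuinely new matches this iteration contributed).
#' @export
postprocess_assignment <- function(assignments, cost_matrix, current_matches,
                                   max_edge_weight) {
  rn <- rownames(cost_matrix); cn <- colnames(cost_matrix)
  keep <- assignments$cost < max_edge_weight
  a <- assignments[keep, , drop = FALSE]
  cand <- data.frame(
    user_id = rn[a$row],
    aed_id = sub("\\|.*$", "", cn[a$col]),
    emergency_id = sub("^[^|]*\\|", "", cn[a$col]),
    travel_time = a$cost, stringsAsFactors = FALSE)
  cand <- cand[!startsWith(cand$user_id, ".dummy") &
                 !startsWith(cand$aed_id, ".dummy"), , drop = FALSE]
  pool <- rbind(current_matches$matches, cand)
  merged <- resolve_conflicts(pool)
  new_ids <- paste(merged$user_id, merged$aed_id, merged$emergency_id)
  old_ids <- paste(current_matches$matches$user_id,
                   current_matches$matches$aed_id,
                   current_matches$matches$emergency_id)
  list(match_set = new_match_set(merged),
       accepted = sum(!(new_ids %in% old_ids)))
}

# keep-the-lower-travel-time conflict resolution on user and AED ids;
# deterministic: ties fall to the lexicographically smaller triple
resolve_conflicts <- function(pool) {
  if (!nrow(pool)) return(pool)
  ord <- order(pool$travel_time, pool$user_id, pool$aed_id,
               pool$emergency_id, method = "radix")
  pool <- pool[ord, , drop = FALSE]
  take <- logical(nrow(pool))
  used_u <- new.env(parent = emptyenv())
  used_a <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(pool))) {
    u <- pool$user_id[i]; a <- pool$aed_id[i]
    if (is.null(used_u[[u]]) && is.null(used_a[[a]])) {
      take[i] <- TRUE
      used_u[[u]] <- TRUE
      used_a[[a]] <- TRUE
    }
  }
  out <- pool[take, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Iterative Hungarian matching of responders to AED-emergency pairs
#'
#' The bipartite baseline: build the combined cost matrix, solve the square
#' assignment problem, post-filter, sentinel out matched users and AEDs, and
#' re-solve until an iteration accepts no new match. Termination is bounded:
#' every productive iteration strictly shrinks the feasible pool.
#'
#' @param scenario an [rns_scenario()].
#' @param provider a [distance_provider()].
#' @param options a [solver_options()]; only determinism-related fields are
#'   used (the bipartite method has no bands, fairness or cap).
#' @return A `match_set` (method `"bm"`) satisfying user-once, AED-once and
#'   battery feasibility; empty scenarios yield an empty match set.
#' @export
match_bipartite <- function(scenario,
                            provider = distance_provider("euclidean"),
                            options = solver_options(method = "bm")) {
  ps <- enumerate_paths(scenario, provider)
  M <- new_match_set(emergency_ids = ps$emergency_ids, method = "bm")
  if (!nrow(ps$paths)) return(M)
  max_iter <- ps$n_available + ps$n_functional + 1L
  for (it in seq_len(max_iter)) {
    cm <- build_cost_matrix(ps, matched_users = M$matches$user_id,
                            matched_aeds = M$matches$aed_id)
    if (is.null(cm)) break
    asg <- hungarian_assign(cm)
    res <- postprocess_assignment(asg, cm, M, ps$max_edge_weight)
    if (res$accepted == 0L) break
    M <- res$match_set
  }
  new_match_set(M$matches, method = "bm", emergency_ids = ps$emergency_ids)
}
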