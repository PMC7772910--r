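#' Build the integer-programming model for responder matching
#'
#' One binary decision variable per battery-feasible candidate path
#' (infeasible paths are filtered out rather than constrained -- the same
#' data-filtering conversion the sliced method uses, keeping the two
#' formulations comparable). Constraints: each user in at most one match,
#' each AED in at most one match, optionally at most `cap` matches per
#' emergency. The objective maximizes the summed inverted travel time
#' `big_time - t`, where `big_time` is the path set's sentinel
#' (max travel time + 1), so every feasible match has value >= 1: minimizing
#' travel time directly would return the empty matching.
#'
#' @param path_set a [enumerate_paths()] (or [slice_paths()]) result.
#' @param options a [solver_options()]; `fairness` and `cap` are read.
#' @param carried matches fixed in earlier solves (a `match_set` or a named
#'   count vector); their per-emergency counts enter the fairness objective
#'   and the cap cumulatively.
#' @return An object of class `rns_ilp`; `n_variables` paths survive the
#'   battery filter. A model with zero variables is the empty-result signal:
#'   [solve_ilp()] returns an empty match set.
#' @export
build_ilp <- function(path_set, options = solver_options("ilp"),
                      carried = NULL) {
  stopifnot(inherits(path_set, "path_set"))
  p <- path_set$paths[path_set$paths$battery_feasible, , drop = FALSE]
  rownames(p) <- NULL
  big <- path_set$max_edge_weight
  emergency_ids <- sort(unique(c(path_set$emergency_ids, p$emergency_id)))
  carried_counts <- carried_to_counts(carried, emergency_ids)
  n_users <- length(unique(p$user_id))
  n_aeds <- length(unique(p$aed_id))
  structure(
    list(paths = p, big_time = big, emergency_ids = emergency_ids,
         fairness = isTRUE(options$fairness), cap = options$cap,
         carried = carried_counts,
         n_variables = nrow(p),
         n_constraints = n_users + n_aeds +
           (if (is.null(options$cap)) 0L else length(emergency_ids))),
    class = "rns_ilp")
}

carried_to_counts <- function(carried, emergency_ids) {
  counts <- stats::setNames(integer(length(emergency_ids)), emergency_ids)
  if (is.null(carried)) return(counts)
  if (inherits(carried, "match_set")) {
    src <- carried$per_emergency_counts
  } else {
    src <- carried
  }
  common <- intersect(names(src), emergency_ids)
  counts[common] <- counts[common] + as.integer(src[common])
  counts
}

#' Add the max-min fairness secondary objective
#'
#' Greedy time-only matching can send every responder to the nearest
#' emergency and leave others unattended. Fairness introduces the auxiliary
#' `MinPair = min_k f(k)` -- the smallest per-emergency match count, with
#' carried-over counts from earlier solves included -- and makes the
#' optimization lexicographic: maximize `MinPair` first, then, holding it at
#' its optimum, maximize the inverted-time objective.
#'
#' @param model an [build_ilp()] model.
#' @param carried optional additional carried matches (see [build_ilp()]).
#' @return The model with fairness enabled.
#' @export
add_fairness <- function(model, carried = NULL) {
  stopifnot(inherits(model, "rns_ilp"))
  model$fairness <- TRUE
  if (!is.null(carried)) {
    model$carried <- model$carried +
      carried_to_counts(carried, model$emergency_ids)
  }
  model
}

#' Cap the number of responders per emergency
#'
#' Adds the constraint `sum_ij x_ijk <= cap` for every emergency `k`
#' (cumulative with carried-over matches in multi-band solves). Useful when
#' a dispatcher wants to stop once enough responders are en route.
#'
#' @param model an [build_ilp()] model.
#' @param cap positive integer.
#' @return The model with the cap set.
#' @export
set_emergency_cap <- function(model, cap) {
  stopifnot(inherits(model, "rns_ilp"))
  cap <- as.integer(cap)
  stopifnot(length(cap) == 1L, cap >= 1L)
  model$cap <- cap
  model$n_constraints <- length(unique(model$paths$user_id)) +
    length(unique(model$paths$aed_id)) + length(model$emergency_ids)
  model
}

#' @export
print.rns_ilp <- function(x, ...) {
  cat(sprintf(
    "<rns_ilp> %d binary variable(s), %d constraint(s)%s%s; big_time %.2f s\n",
    x$n_variables, x$n_constraints,
    if (x$fairness) ", max-min fairness" else "",
    if (is.null(x$cap)) "" else sprintf(", cap %d/emergency", x$cap),
    x$big_time))
  invisible(x)
}

## ---- internal solver machinery ------------------------------------------

# index the model's variables for the combinatorial solvers
ilp_prep <- function(model) {
  p <- model$paths
  users <- sort(unique(p$user_id))
  aeds <- sort(unique(p$aed_id))
  emergencies <- model$emergency_ids
  ui <- match(p$user_id, users)
  ai <- match(p$aed_id, aeds)
  ei <- match(p$emergency_id, emergencies)
  v <- model$big_time - p$travel_time
  # candidate paths per user, in lexicographic (AED, emergency) order --
  # this DFS order is the canonical tie-break shared by all solvers
  ord <- order(ui, ai, ei, method = "radix")
  cand <- split(ord, factor(ui[ord], levels = seq_along(users)))
  list(paths = p, users = users, aeds = aeds, emergencies = emergencies,
       ui = ui, ai = ai, ei = ei, v = v, t = p$travel_time, cand = cand)
}

# Exact solve of the plain inverted-time objective by reduction to a
# rectangular linear sum assignment problem: since emergencies are
# unconstrained, an optimal solution uses, for any chosen (user, AED) pair,
# that pair's best emergency; the remainder is a max-weight bipartite
# matching of users to AEDs with weights big - min_k t (0 where no feasible
# path), which a zero-weight-dropping LSAP solves to optimality.
solve_ilp_lsap <- function(prep, big) {
  nU <- length(prep$users); nA <- length(prep$aeds)
  key <- (prep$ui - 1L) * nA + prep$ai
  ord <- order(key, prep$t, prep$ei, method = "radix")
  first <- ord[!duplicated(key[ord])]
  w <- matrix(0, nU, nA)
  w[cbind(prep$ui[first], prep$ai[first])] <- big - prep$t[first]
  best_path <- matrix(NA_integer_, nU, nA)
  best_path[cbind(prep$ui[first], prep$ai[first])] <- first
  if (nU <= nA) {
    sol <- clue::solve_LSAP(w, maximum = TRUE)
    rows <- seq_len(nU); cols <- as.integer(sol)
  } else {
    sol <- clue::solve_LSAP(t(w), maximum = TRUE)
    cols <- seq_len(nA); rows <- as.integer(sol)
  }
  keep <- w[cbind(rows, cols)] > 0
  best_path[cbind(rows[keep], cols[keep])]
}

# depth-first branch-and-bound over users; exact for the capped and/or
# fairness-constrained variants. mode "value" maximizes the inverted-time
# sum (optionally subject to min per-emergency count >= min_req); mode
# "minpair" maximizes the minimum per-emergency count. Bounds are
# admissible, so optimality is preserved; the first optimum in canonical
# DFS order is kept, making results deterministic.
# quick feasible balanced solution used to seed the branch-and-bound: give
# the emergency with the lowest cumulative count its first available
# candidate, round after round
greedy_balanced <- function(prep, carried, cap = NULL) {
  U <- length(prep$users); A <- length(prep$aeds)
  K <- length(prep$emergencies)
  cand_all <- unlist(prep$cand, use.names = FALSE)   # canonical order
  aed_used <- logical(A); user_used <- logical(U)
  counts <- carried; sel <- integer(0)
  repeat {
    progressed <- FALSE
    for (k in order(counts, seq_len(K))) {
      if (!is.null(cap) && counts[k] >= cap) next
      for (p in cand_all) {
        if (prep$ei[p] != k || user_used[prep$ui[p]] || aed_used[prep$ai[p]]) next
        sel <- c(sel, p)
        user_used[prep$ui[p]] <- TRUE; aed_used[prep$ai[p]] <- TRUE
        counts[k] <- counts[k] + 1L
        progressed <- TRUE
        break
      }
      if (progressed) break
    }
    if (!progressed) break
  }
  list(selection = sel, counts = counts,
       minpair = if (K) min(counts) else 0L)
}

ilp_bb <- function(prep, carried, cap = NULL, mode = c("value", "minpair"),
                   min_req = NULL, init_selection = NULL) {
  mode <- match.arg(mode)
  U <- length(prep$users); A <- length(prep$aeds)
  K <- length(prep$emergencies)
  v <- prep$v; ai <- prep$ai; ei <- prep$ei
  # explore each user's fastest paths first: good incumbents appear early
  # and the value bound prunes sooner; ties stay lexicographic
  cand <- lapply(prep$cand, function(idx)
    idx[order(prep$t[idx], ai[idx], ei[idx], method = "radix")])
  best_u <- vapply(seq_len(U), function(u)
    if (length(cand[[u]])) max(v[cand[[u]]]) else 0, numeric(1))
  # topk[u, q+1]: sum of the q largest per-user best values among users
  # u..U, q capped at the AED count -- an admissible bound on the value the
  # remaining users can still add when q AEDs are unused
  topk <- matrix(0, U + 1L, A + 1L)
  vals <- numeric(0)
  for (u in rev(seq_len(U))) {
    vals <- sort(c(vals, best_u[u]), decreasing = TRUE)
    if (length(vals) > A) vals <- vals[seq_len(A)]
    topk[u, seq_len(length(vals)) + 1L] <- cumsum(vals)
    if (length(vals) < A) {
      topk[u, (length(vals) + 2L):(A + 1L)] <- topk[u, length(vals) + 1L]
    }
  }
  has_k <- matrix(FALSE, U, K)
  for (u in seq_len(U)) has_k[u, unique(ei[cand[[u]]])] <- TRUE
  rem_k <- matrix(0L, U + 1L, K)                         # rem_k[u, k]: users >= u with a path to k
  for (u in rev(seq_len(U))) rem_k[u, ] <- rem_k[u + 1L, ] + has_k[u, ]

  aed_used <- logical(A)
  counts <- carried                                      # integer, length K
  sel <- integer(U)
  n_aed_avail <- A
  cur_value <- 0
  best_value <- -Inf; best_minpair <- -1L; best_sel <- integer(U)
  have_incumbent <- FALSE

  # seed the incumbent with a known-feasible selection (greedy or a
  # previous stage's optimum) so pruning is active from the first node
  if (!is.null(init_selection) && length(init_selection)) {
    icounts <- carried
    for (p in init_selection) icounts[ei[p]] <- icounts[ei[p]] + 1L
    imp <- if (K) min(icounts) else 0L
    if (is.null(min_req) || imp >= min_req) {
      best_sel[prep$ui[init_selection]] <- init_selection
      best_value <- sum(v[init_selection])
      best_minpair <- imp
      have_incumbent <- TRUE
    } else {
      best_sel <- integer(U)
    }
  }

  # highest minimum per-emergency count still reachable from this node:
  # each emergency k can gain at most capadd[k] matches, and at most
  # `budget` matches can be added in total (water-filling bound)
  minpair_ub <- function(u) {
    budget <- min(U - u + 1L, n_aed_avail)
    capadd <- pmin(rem_k[u, ], n_aed_avail)
    if (!is.null(cap)) capadd <- pmin(capadd, cap - counts)
    m <- min(counts + capadd)
    while (m > 0L && sum(pmax(0L, m - counts)) > budget) m <- m - 1L
    m
  }

  rec <- function(u) {
    if (u > U) {
      mp <- if (K) min(counts) else 0L
      if (!is.null(min_req) && mp < min_req) return(invisible())
      if (mode == "value") {
        if (cur_value > best_value + 1e-9) {
          best_value <<- cur_value; best_sel <<- sel; have_incumbent <<- TRUE
        }
      } else {
        if (mp > best_minpair) {
          best_minpair <<- mp; best_sel <<- sel; have_incumbent <<- TRUE
        }
      }
      return(invisible())
    }
    # admissible bounds / feasibility pruning
    if (K && (!is.null(min_req) || mode == "minpair")) {
      ub <- minpair_ub(u)
      if (!is.null(min_req) && ub < min_req) return(invisible())
      if (mode == "minpair" && have_incumbent && ub <= best_minpair) {
        return(invisible())
      }
    }
    if (mode == "value" && have_incumbent &&
        cur_value + topk[u, n_aed_avail + 1L] <= best_value + 1e-9) {
      return(invisible())
    }
    for (p in cand[[u]]) {
      a <- ai[p]; k <- ei[p]
      if (aed_used[a]) next
      if (!is.null(cap) && counts[k] >= cap) next
      aed_used[a] <<- TRUE; counts[k] <<- counts[k] + 1L
      n_aed_avail <<- n_aed_avail - 1L
      sel[u] <<- p; cur_value <<- cur_value + v[p]
      rec(u + 1L)
      aed_used[a] <<- FALSE; counts[k] <<- counts[k] - 1L
      n_aed_avail <<- n_aed_avail + 1L
      sel[u] <<- 0L; cur_value <<- cur_value - v[p]
    }
    rec(u + 1L)                                          # leave user u unmatched
    invisible()
  }
  rec(1L)
  list(selection = best_sel[best_sel > 0L],
       value = if (mode == "value") best_value else NA_real_,
       minpair = if (mode == "minpair") best_minpair else NA_integer_)
}

# Exact solver for the fairness value stage: depth-first enumeration of
# AED-to-emergency plans (each AED serves one emergency or is unused), with
# admissible value and count-deficit pruning; each surviving plan reduces to
# a linear sum assignment of users to the planned (AED, emergency) columns.
# Exponential in the AED count, not the user count -- the right trade-off
# for responder networks, where AEDs are the scarce resource.
ilp_fair_value <- function(prep, carried, cap = NULL, min_req = 0L,
                           init_selection = NULL) {
  U <- length(prep$users); A <- length(prep$aeds)
  K <- length(prep$emergencies)
  W <- array(0, c(U, A, K))                    # value per triple, 0 = infeasible
  pidx <- array(0L, c(U, A, K))                # back-map to path rows
  W[cbind(prep$ui, prep$ai, prep$ei)] <- prep$v
  pidx[cbind(prep$ui, prep$ai, prep$ei)] <- seq_along(prep$v)
  bestjk <- apply(W, c(2L, 3L), max)           # A x K: best user value per column
  if (K == 1L) bestjk <- matrix(bestjk, A, 1L)
  rem_best <- c(rev(cumsum(rev(pmax(apply(bestjk, 1L, max), 0)))), 0)

  best_value <- -Inf; best_sel <- integer(0)
  if (!is.null(init_selection) && length(init_selection)) {
    best_value <- sum(prep$v[init_selection])
    best_sel <- init_selection
  }
  plan <- integer(A); assigned <- integer(K); assigned_ub <- 0
  L <- (max(prep$v) + 1) * (A + 1)             # cardinality-dominant offset

  eval_plan <- function() {
    used <- which(plan > 0L)
    counts <- carried + assigned
    if (min(counts) < min_req) return(invisible())
    if (length(used) > U) return(invisible())
    if (length(used)) {
      M <- matrix(W[cbind(rep(seq_len(U), length(used)),
                          rep(used, each = U),
                          rep(plan[used], each = U))], U, length(used))
      if (any(colSums(M > 0) == 0L)) return(invisible())  # unmatched AED
      Wb <- ifelse(M > 0, L + M, 0)
      sol <- clue::solve_LSAP(t(Wb), maximum = TRUE)      # rows = used AEDs
      rows <- as.integer(sol)                             # chosen users
      picked <- M[cbind(rows, seq_along(used))]
      if (any(picked <= 0)) return(invisible())           # plan not realizable
      value <- sum(picked)
      if (value > best_value + 1e-9) {
        best_value <<- value
        best_sel <<- pidx[cbind(rows, used, plan[used])]
      }
    } else if (0 > best_value) {
      best_value <<- 0; best_sel <<- integer(0)
    }
    invisible()
  }

  rec <- function(j) {
    if (j > A) return(eval_plan())
    # count deficit: remaining AEDs must be able to lift every emergency
    # to min_req
    deficit <- sum(pmax(0L, min_req - (carried + assigned)))
    if (deficit > A - j + 1L) return(invisible())
    if (assigned_ub + rem_best[j] <= best_value + 1e-9) return(invisible())
    for (k in seq_len(K)) {
      if (bestjk[j, k] <= 0) next
      if (!is.null(cap) && carried[k] + assigned[k] >= cap) next
      plan[j] <<- k; assigned[k] <<- assigned[k] + 1L
      assigned_ub <<- assigned_ub + bestjk[j, k]
      rec(j + 1L)
      plan[j] <<- 0L; assigned[k] <<- assigned[k] - 1L
      assigned_ub <<- assigned_ub - bestjk[j, k]
    }
    rec(j + 1L)                                # AED j unused
  }
  rec(1L)
  list(selection = best_sel, value = best_value)
}

selection_to_match_set <- function(prep, selection, model, method) {
  m <- prep$paths[selection, c("user_id", "aed_id", "emergency_id",
                               "travel_time"), drop = FALSE]
  ms <- new_match_set(m, method = method, emergency_ids = model$emergency_ids)
  ms$objective <- sum(model$big_time - m$travel_time)
  ms$min_pair <- if (length(model$emergency_ids)) {
    min(model$carried + ms$per_emergency_counts[model$emergency_ids])
  } else 0L
  ms
}

#' Solve the matching model to proven optimality
#'
#' Without fairness or cap the model reduces exactly to a rectangular
#' assignment problem (each chosen user-AED pair takes its best emergency)
#' and is solved by the Hungarian method; with a per-emergency cap and/or
#' the lexicographic fairness objective it is solved by an exact
#' branch-and-bound with admissible bounds. Either way the returned solution
#' attains the stated optimum; ties are broken canonically so results are
#' reproducible.
#'
#' @param model an [build_ilp()] model.
#' @return A `match_set` (method `"ilp"`) carrying the achieved objective in
#'   `$objective` and, with fairness, the attained minimum per-emergency
#'   count in `$min_pair`.
#' @export
solve_ilp <- function(model) {
  stopifnot(inherits(model, "rns_ilp"))
  if (model$n_variables == 0L) {
    ms <- new_match_set(method = "ilp", emergency_ids = model$emergency_ids)
    ms$objective <- 0
    ms$min_pair <- if (length(model$emergency_ids)) min(model$carried) else 0L
    return(ms)
  }
  prep <- ilp_prep(model)
  if (!model$fairness && is.null(model$cap)) {
    selection <- solve_ilp_lsap(prep, model$big_time)
  } else if (!model$fairness) {
    selection <- ilp_bb(prep, carried = model$carried, cap = model$cap,
                        mode = "value")$selection
  } else {
    seed <- greedy_balanced(prep, model$carried, model$cap)
    stage1 <- ilp_bb(prep, carried = model$carried, cap = model$cap,
                     mode = "minpair", init_selection = seed$selection)
    stage2 <- ilp_fair_value(prep, carried = model$carried, cap = model$cap,
                             min_req = stage1$minpair,
                             init_selection = stage1$selection)
    selection <- stage2$selection
  }
  selection_to_match_set(prep, selection, model, method = "ilp")
}

#' One-shot exact matching of a scenario
#'
#' Convenience wrapper: enumerate paths, build the model (fairness and cap
#' from `options`), solve.
#'
#' @param scenario an [rns_scenario()].
#' @param provider a [distance_provider()].
#' @param options a [solver_options()].
#' @return A `match_set` (method `"ilp"`).
#' @export
match_ilp <- function(scenario, provider = distance_provider("euclidean"),
                      options = solver_options("ilp")) {
  ps <- enumerate_paths(scenario, provider)
  solve_ilp(build_ilp(ps, options))
}

#' Exhaustive brute-force matching (verification oracle)
#'
#' Enumerates every user-disjoint, AED-disjoint subset of the feasible paths
#' by plain recursion -- no bounds, no pruning beyond the constraints -- and
#' returns the subset maximizing the same objective as [solve_ilp()]
#' (lexicographic minimum-count-then-time when fairness is on). Exists so
#' the optimized solvers can be verified against an independent route;
#' guarded to small instances.
#'
#' @param path_set a [enumerate_paths()] result with
#'   `n_available * n_functional * n_emergencies <= 200`.
#' @param options a [solver_options()]; `fairness` and `cap` are honored.
#' @param carried optional carried matches (as in [build_ilp()]).
#' @return A `match_set` (method `"oracle"`) with `$objective` and
#'   `$min_pair`.
#' @export
brute_force_match <- function(path_set, options = solver_options("ilp"),
                              carried = NULL) {
  stopifnot(inherits(path_set, "path_set"))
  size <- path_set$n_available * path_set$n_functional * path_set$n_emergencies
  if (size > 200) {
    stop("brute_force_match is an oracle for small instances only ",
         "(n*m*o <= 200); got ", size, call. = FALSE)
  }
  model <- build_ilp(path_set, options, carried)
  if (model$n_variables == 0L) {
    ms <- new_match_set(method = "oracle", emergency_ids = model$emergency_ids)
    ms$objective <- 0
    ms$min_pair <- if (length(model$emergency_ids)) min(model$carried) else 0L
    return(ms)
  }
  prep <- ilp_prep(model)
  U <- length(prep$users); A <- length(prep$aeds)
  K <- length(prep$emergencies)
  cand <- prep$cand; v <- prep$v; ai <- prep$ai; ei <- prep$ei
  cap <- model$cap; fair <- model$fairness
  aed_used <- logical(A); counts <- model$carried; sel <- integer(U)
  cur_value <- 0
  best_key <- c(-Inf, -Inf); best_sel <- integer(U)
  rec <- function(u) {
    if (u > U) {
      mp <- if (K) min(counts) else 0L
      key <- if (fair) c(mp, cur_value) else c(0, cur_value)
      if (key[1L] > best_key[1L] + 1e-9 ||
          (abs(key[1L] - best_key[1L]) <= 1e-9 &&
           key[2L] > best_key[2L] + 1e-9)) {
        best_key <<- key; best_sel <<- sel
      }
      return(invisible())
    }
    for (p in cand[[u]]) {
      a <- ai[p]; k <- ei[p]
      if (aed_used[a]) next
      if (!is.null(cap) && counts[k] >= cap) next
      aed_used[a] <<- TRUE; counts[k] <<- counts[k] + 1L
      sel[u] <<- p; cur_value <<- cur_value + v[p]
      rec(u + 1L)
      aed_used[a] <<- FALSE; counts[k] <<- counts[k] - 1L
      sel[u] <<- 0L; cur_value <<- cur_value - v[p]
    }
    rec(u + 1L)
    invisible()
  }
  rec(1L)
  ms <- selection_to_match_set(prep, best_sel[best_sel > 0L], model,
                               method = "oracle")
  ms
}

#' Dump the model as LP-format text
#'
#' Writes the constructed model (objective, user-once, AED-once and cap
#' constraints, binary variable declarations) in CPLEX LP format for audit
#' with any external solver.
#'
#' @param model an [build_ilp()] model.
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_lp <- function(model, path) {
  stopifnot(inherits(model, "rns_ilp"))
  p <- model$paths
  var <- sprintf("x_%s_%s_%s", p$user_id, p$aed_id, p$emergency_id)
  var <- gsub("[^A-Za-z0-9_]", "_", var)
  con <- file(path, "w"); on.exit(close(con))
  writeLines("Maximize", con)
  writeLines(paste(" obj:",
                   paste(sprintf("%.12g %s", model$big_time - p$travel_time,
                                 var), collapse = " + ")), con)
  writeLines("Subject To", con)
  i <- 0L
  for (u in unique(p$user_id)) {
    i <- i + 1L
    writeLines(sprintf(" user_%d: %s <= 1", i,
                       paste(var[p$user_id == u], collapse = " + ")), con)
  }
  for (a in unique(p$aed_id)) {
    i <- i + 1L
    writeLines(sprintf(" aed_%d: %s <= 1", i,
                       paste(var[p$aed_id == a], collapse = " + ")), con)
  }
  if (!is.null(model$cap)) {
    for (k in model$emergency_ids) {
      sub <- var[p$emergency_id == k]
      if (!length(sub)) next
      i <- i + 1L
      writeLines(sprintf(" cap_%d: %s <= %d", i,
                         paste(sub, collapse = " + "),
                         model$cap - model$carried[[k]]), con)
    }
  }
  writeLines("Binary", con)
  writeLines(paste("", paste(var, collapse = " ")), con)
  writeLines("End", con)
  invisible(path)
}
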