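#' Match responders, AEDs and emergencies
#'
#' The front door of the package: dispatches a scenario to one of the three
#' solvers.
#'
#' \describe{
#'   \item{`"ppilp"`}{travel-time-sliced exact matching
#'     ([match_preprocessed()]): solves in ascending time bands, fast, the
#'     recommended method.}
#'   \item{`"ilp"`}{one-shot exact matching ([match_ilp()]).}
#'   \item{`"bm"`}{iterative Hungarian matching over combined
#'     (AED, emergency) columns ([match_bipartite()]).}
#' }
#'
#' @param scenario an [rns_scenario()] or a path accepted by
#'   [load_scenario()].
#' @param method `"ppilp"`, `"ilp"` or `"bm"`; defaults to
#'   `options$method`.
#' @param provider a [distance_provider()].
#' @param options a [solver_options()].
#' @return A `match_set`.
#' @examples
#' scn <- generate_scenario(50, 2, 1, seed = 7)
#' match_responders(scn, method = "ppilp")
#' @export
match_responders <- function(scenario, method = NULL,
                             provider = distance_provider("euclidean"),
                             options = solver_options()) {
  if (is.character(scenario)) scenario <- load_scenario(scenario)
  stopifnot(inherits(scenario, "rns_scenario"))
  method <- method %||% options$method
  method <- match.arg(method, c("ppilp", "ilp", "bm"))
  switch(method,
    ppilp = match_preprocessed(scenario, provider, options),
    ilp = {
      ps <- enumerate_paths(scenario, provider)
      solve_ilp(build_ilp(ps, options))
    },
    bm = match_bipartite(scenario, provider, options))
}

#' Run one matching job end to end
#'
#' Loads a scenario, solves it with the chosen method, optionally writes the
#' matches, and returns a run report: the method, an echo of the options,
#' the match records, the summary (total match time, per-emergency counts,
#' unique emergencies covered) and the elapsed wall-clock time
#' (informational only -- never asserted).
#'
#' @param scenario_path scenario file or directory, or an [rns_scenario()].
#' @param method `"ppilp"`, `"ilp"` or `"bm"`.
#' @param options a [solver_options()].
#' @param provider a [distance_provider()].
#' @param out optional path for [save_matches()].
#' @param format scenario format forwarded to [load_scenario()].
#' @return An object of class `run_report`.
#' @export
run_match <- function(scenario_path, method = NULL,
                      options = solver_options(),
                      provider = distance_provider("euclidean"),
                      out = NULL, format = NULL) {
  scenario <- if (inherits(scenario_path, "rns_scenario")) scenario_path
              else load_scenario(scenario_path, format = format)
  method <- method %||% options$method
  elapsed <- system.time(
    ms <- match_responders(scenario, method, provider, options))[["elapsed"]]
  if (!is.null(out)) save_matches(ms, out)
  structure(
    list(method = method, options = options, matches = ms$matches,
         summary = match_summary(ms), match_set = ms,
         timing_s = unname(elapsed)),
    class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<run_report> method %s: %d match(es), total %.2f s, %d emergenc%s covered\n",
              x$method, s$n_matches, s$total_match_time,
              s$unique_emergencies_covered,
              if (s$unique_emergencies_covered == 1L) "y" else "ies"))
  if (length(s$per_emergency_counts)) {
    cat("  per emergency:",
        paste(sprintf("%s=%d", names(s$per_emergency_counts),
                      s$per_emergency_counts), collapse = ", "), "\n")
  }
  cat(sprintf("  elapsed %.3f s (informational)\n", x$timing_s))
  invisible(x)
}

#' Compare the three matching methods on one scenario
#'
#' Runs the iterative Hungarian, one-shot exact, and travel-time-sliced
#' solvers on the same scenario and tabulates match count, total match time
#' and unique emergencies covered per method -- the comparison used to
#' evaluate responder-matching engines. Fairness, when requested via
#' `options`, is applied to the sliced method only (mirroring how the
#' benchmark applies the secondary objective), unless `fair_all = TRUE`.
#'
#' @param scenario an [rns_scenario()] or a path accepted by
#'   [load_scenario()].
#' @param options a [solver_options()].
#' @param provider a [distance_provider()].
#' @param fair_all apply the fairness objective to all three methods'
#'   exact counterparts (the bipartite method has no fairness notion and is
#'   always time-only).
#' @return A list of class `run_comparison`: `table` (one row per method)
#'   and `reports` (the three `run_report`s).
#' @export
run_compare <- function(scenario, options = solver_options(),
                        provider = distance_provider("euclidean"),
                        fair_all = FALSE) {
  if (is.character(scenario)) scenario <- load_scenario(scenario)
  opts_plain <- options
  opts_plain$fairness <- if (fair_all) options$fairness else FALSE
  reports <- list(
    bm = run_match(scenario, "bm", opts_plain, provider),
    ilp = run_match(scenario, "ilp", opts_plain, provider),
    ppilp = run_match(scenario, "ppilp", options, provider))
  tab <- do.call(rbind, lapply(names(reports), function(m) {
    s <- reports[[m]]$summary
    data.frame(method = m, n_matches = s$n_matches,
               total_match_time = s$total_match_time,
               unique_emergencies_covered = s$unique_emergencies_covered,
               timing_s = reports[[m]]$timing_s,
               stringsAsFactors = FALSE)
  }))
  structure(list(table = tab, reports = reports), class = "run_comparison")
}

#' @export
print.run_comparison <- function(x, ...) {
  cat("<run_comparison>\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}
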