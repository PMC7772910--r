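# Fixture builders shared across test files. Everything is constructed in
# code; no data files.

# a small hand-positioned scenario: 3 users, 2 AEDs, 2 emergencies
tiny_scenario <- function(battery_level = 100, rate = 0.01) {
  rns_scenario(
    users = data.frame(
      id = c("u1", "u2", "u3"),
      x = c(0, 100, 200), y = c(0, 0, 0),
      walking_speed = c(1.0, 1.25, 1.5),
      battery_level = battery_level,
      battery_consumption_rate = rate,
      available = TRUE),
    aeds = data.frame(id = c("a1", "a2"), x = c(50, 150), y = c(0, 0),
                      functional = TRUE),
    emergencies = data.frame(id = c("e1", "e2"), x = c(100, 250), y = c(0, 0)))
}

# n-user / m-AED / o-emergency random instance with a mixed battery profile;
# wraps the package generator with small sizes for oracle work
small_instance <- function(n, m, o, seed) {
  generate_scenario(generator_spec(
    n, m, o, seed = seed,
    battery_level_range = c(5, 100),
    battery_rate_range = c(0.005, 0.05)))
}

# assert every MatchSet invariant plus battery feasibility against a path set
expect_valid_match_set <- function(ms, ps = NULL, horizon = NULL) {
  m <- ms$matches
  expect_equal(anyDuplicated(m$user_id), 0L)
  expect_equal(anyDuplicated(m$aed_id), 0L)
  expect_true(all(is.finite(m$travel_time)))
  expect_true(all(m$travel_time >= 0))
  expect_equal(sum(m$travel_time), ms$total_match_time)
  expect_equal(sum(ms$per_emergency_counts), nrow(m))
  if (!is.null(ps)) {
    expect_true(all(m$travel_time < ps$max_edge_weight))
    if (nrow(m)) {
      key <- paste(m$user_id, m$aed_id, m$emergency_id)
      pk <- paste(ps$paths$user_id, ps$paths$aed_id, ps$paths$emergency_id)
      idx <- match(key, pk)
      expect_false(anyNA(idx))
      expect_true(all(ps$paths$battery_feasible[idx]))
      expect_equal(m$travel_time, ps$paths$travel_time[idx])
    }
  }
  if (!is.null(horizon)) expect_true(all(m$travel_time <= horizon))
  invisible(ms)
}
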