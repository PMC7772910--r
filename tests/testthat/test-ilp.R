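# model construction, exact solving, fairness, caps, oracle equivalence

test_that("model size follows the battery-filtered variable count", {
  scn <- tiny_scenario()
  ps <- enumerate_paths(scn)
  model <- build_ilp(ps)
  expect_equal(model$n_variables, nrow(ps$paths))       # all feasible here
  expect_equal(model$n_constraints, 3L + 2L)            # user-once + AED-once
  expect_true(all(model$big_time - model$paths$travel_time >= 1))

  # 1 x 1 x 1 -> one variable, two constraints
  s1 <- rns_scenario(scn$users[1, , drop = FALSE],
                     scn$aeds[1, , drop = FALSE],
                     scn$emergencies[1, , drop = FALSE])
  m1 <- build_ilp(enumerate_paths(s1))
  expect_equal(m1$n_variables, 1L)
  expect_equal(m1$n_constraints, 2L)

  # every path battery-infeasible -> empty model -> empty solution
  dead <- build_ilp(enumerate_paths(tiny_scenario(battery_level = 1e-9,
                                                  rate = 1)))
  expect_equal(dead$n_variables, 0L)
  expect_equal(nrow(solve_ilp(dead)$matches), 0L)
})

test_that("forced optima are found and decoded deterministically", {
  # two users competing for one AED: the faster one wins
  users <- data.frame(id = c("u1", "u2"), x = c(100, 80), y = 0,
                      walking_speed = 1, battery_level = 100,
                      battery_consumption_rate = 0.01, available = TRUE)
  aeds <- data.frame(id = "a1", x = 0, y = 0, functional = TRUE)
  eme <- data.frame(id = "e1", x = 0, y = 0)
  ms <- match_ilp(rns_scenario(users, aeds, eme))
  expect_equal(ms$matches$user_id, "u2")
  expect_equal(ms$matches$travel_time, 80)

  # disjoint user/AED pairs all matched
  scn <- tiny_scenario()
  ms2 <- match_ilp(scn)
  expect_equal(nrow(ms2$matches), 2L)

  # repeat solves give identical output
  expect_identical(match_ilp(scn)$matches, ms2$matches)
})

test_that("ILP equals the exhaustive oracle on seeded instances (property)", {
  mismatches <- 0L
  for (seed in 1:25) {
    n <- (seed %% 4) + 2L; m <- (seed %% 3) + 1L; o <- (seed %% 3) + 1L
    ps <- enumerate_paths(small_instance(n, m, o, 500 + seed))
    for (fair in c(FALSE, TRUE)) {
      op <- solver_options("ilp", fairness = fair)
      ilp <- solve_ilp(build_ilp(ps, op))
      bf <- brute_force_match(ps, op)
      expect_valid_match_set(ilp, ps)
      if (!isTRUE(all.equal(ilp$objective, bf$objective)) ||
          (fair && ilp$min_pair != bf$min_pair)) {
        mismatches <- mismatches + 1L
      }
    }
  }
  expect_equal(mismatches, 0L)
})

test_that("fairness trades total time for coverage on the showcase scenario", {
  scn <- special_case_scenario()
  ps <- enumerate_paths(scn)
  expect_equal(nrow(ps$paths), 32L)
  expect_true(all(ps$paths$battery_feasible))

  greedy <- match_ilp(scn)
  expect_equal(unname(greedy$per_emergency_counts[c("e1", "e2")]), c(4L, 0L))
  expect_equal(greedy$total_match_time, 240, tolerance = 1e-9)

  fair <- match_ilp(scn, options = solver_options("ilp", fairness = TRUE))
  expect_equal(unname(fair$per_emergency_counts[c("e1", "e2")]), c(2L, 2L))
  expect_equal(fair$total_match_time, 260, tolerance = 1e-9)
  expect_equal(fair$min_pair, 2L)

  # no alternative solution has a larger minimum count (oracle check)
  bf <- brute_force_match(ps, solver_options("ilp", fairness = TRUE))
  expect_equal(bf$min_pair, 2L)

  # with a single emergency MinPair is just the match count
  one <- rns_scenario(scn$users, scn$aeds,
                      scn$emergencies[1, , drop = FALSE])
  f1 <- match_ilp(one, options = solver_options("ilp", fairness = TRUE))
  p1 <- match_ilp(one)
  expect_equal(f1$min_pair, nrow(f1$matches))
  expect_equal(nrow(f1$matches), nrow(p1$matches))
})

test_that("per-emergency caps bind exactly and compose with fairness", {
  scn <- generate_scenario(generator_spec(10, 10, 1, seed = 77,
                                          battery_level_range = c(100, 100),
                                          battery_rate_range = c(1e-4, 1e-4)))
  ps <- enumerate_paths(scn)
  capped <- solve_ilp(set_emergency_cap(build_ilp(ps), 3L))
  expect_equal(nrow(capped$matches), 3L)
  # cap above the feasible count changes nothing
  loose <- solve_ilp(set_emergency_cap(build_ilp(ps), 100L))
  expect_equal(loose$matches, match_ilp(scn)$matches)

  # cap 1 with fairness on a 4x4x2 instance: one match per emergency
  scn2 <- small_instance(4, 4, 2, seed = 42)
  ps2 <- enumerate_paths(scn2)
  op <- solver_options("ilp", fairness = TRUE, cap = 1L)
  sol <- solve_ilp(build_ilp(ps2, op))
  bf <- brute_force_match(ps2, op)
  expect_equal(sol$objective, bf$objective, tolerance = 1e-9)
  expect_equal(sol$min_pair, bf$min_pair)
  expect_true(all(sol$per_emergency_counts <= 1L))
})

test_that("adding a user or AED never decreases the match count (property)", {
  for (seed in c(21, 22, 23)) {
    scn <- small_instance(4, 3, 2, seed)
    base <- nrow(match_ilp(scn)$matches)
    extra_user <- scn$users[1, ]
    extra_user$id <- "u9999"; extra_user$battery_level <- 100
    grown_u <- rns_scenario(rbind(scn$users, extra_user), scn$aeds,
                            scn$emergencies)
    expect_gte(nrow(match_ilp(grown_u)$matches), base)
    extra_aed <- data.frame(id = "a9999", x = scn$aeds$x[1] + 1,
                            y = scn$aeds$y[1], functional = TRUE)
    grown_a <- rns_scenario(scn$users, rbind(scn$aeds, extra_aed),
                            scn$emergencies)
    expect_gte(nrow(match_ilp(grown_a)$matches), base)
  }
})

test_that("the oracle refuses oversized instances and handles empties", {
  big <- generate_scenario(generator_spec(10, 10, 3, seed = 1))
  expect_error(brute_force_match(enumerate_paths(big)), "small instances")
  empty <- enumerate_paths(rns_scenario(NULL, NULL, NULL))
  expect_equal(nrow(brute_force_match(empty)$matches), 0L)
})

test_that("match summaries count unique emergencies covered", {
  ms <- new_match_set(data.frame(
    user_id = c("u1", "u2"), aed_id = c("a1", "a2"),
    emergency_id = c("e1", "e1"), travel_time = c(1, 2)),
    emergency_ids = c("e1", "e2"))
  s <- match_summary(ms)
  expect_equal(s$unique_emergencies_covered, 1L)
  expect_equal(unname(s$per_emergency_counts), c(2L, 0L))
  s4 <- match_summary(new_match_set(data.frame(
    user_id = paste0("u", 1:4), aed_id = paste0("a", 1:4),
    emergency_id = c("e1", "e1", "e2", "e2"), travel_time = 1:4)))
  expect_equal(s4$unique_emergencies_covered, 2L)
  expect_equal(match_summary(new_match_set())$total_match_time, 0)
})

test_that("the LP-format dump reflects the model structure", {
  ps <- enumerate_paths(tiny_scenario())
  model <- set_emergency_cap(build_ilp(ps), 2L)
  f <- withr::local_tempfile(fileext = ".lp")
  write_lp(model, f)
  txt <- readLines(f)
  expect_equal(sum(grepl("^ user_", txt)), 3L)
  expect_equal(sum(grepl("^ aed_", txt)), 2L)
  expect_equal(sum(grepl("^ cap_", txt)), 2L)
  expect_true(any(txt == "Binary"))
})
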