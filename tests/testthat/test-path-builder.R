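# travel-time model, battery feasibility, path enumeration, radius baseline

test_that("travel_time is distance via the AED over walking speed", {
  u <- list(id = "u", x = 0, y = 0, walking_speed = 1.2,
            battery_level = 50, battery_consumption_rate = 0.01)
  a <- list(id = "a", x = 60, y = 0)
  e <- list(id = "e", x = 120, y = 0)
  expect_equal(travel_time(u, a, e), 100)

  # all collocated -> zero seconds
  z <- list(id = "z", x = 5, y = 5)
  u0 <- modifyList(u, list(x = 5, y = 5))
  expect_equal(travel_time(u0, z, z), 0)

  expect_error(travel_time(modifyList(u, list(walking_speed = 0)), a, e),
               "walking_speed")
})

test_that("matrix mode reproduces route distance, not straight-line", {
  # straight-line separation 100 m but tabulated walking route 600 m
  users <- data.frame(id = "u1", x = 0, y = 0, walking_speed = 1.0,
                      battery_level = 100, battery_consumption_rate = 0.01)
  aeds <- data.frame(id = "a1", x = 100, y = 0)
  emergencies <- data.frame(id = "e1", x = 100, y = 0)
  dm <- list(
    user_aed = matrix(600, 1, 1, dimnames = list("u1", "a1")),
    aed_emergency = matrix(0, 1, 1, dimnames = list("a1", "e1")))
  scn <- rns_scenario(users, aeds, emergencies, distance_matrix = dm)
  prov <- distance_provider("matrix")
  expect_equal(travel_time(users, aeds, emergencies, prov, scn), 600)
  expect_equal(travel_time(users, aeds, emergencies,
                           distance_provider("euclidean"), scn), 100)
  # missing entry is a configuration error
  scn2 <- scn
  rownames(scn2$distance_matrix$user_aed) <- "uX"
  expect_error(enumerate_paths(scn2, prov), "missing entries")
})

test_that("powered time and battery feasibility follow the level/rate ratio", {
  u <- list(id = "u", battery_level = 50, battery_consumption_rate = 0.05)
  expect_equal(powered_time(u), 1000)
  expect_equal(powered_time(list(battery_level = 0,
                                 battery_consumption_rate = 0.1)), 0)
  expect_equal(powered_time(list(battery_level = 100,
                                 battery_consumption_rate = 0.1)), 1000)
  expect_error(powered_time(list(battery_level = 10,
                                 battery_consumption_rate = 0)),
               "battery_consumption_rate")

  # boundary is inclusive: dying exactly on arrival still counts
  expect_true(battery_feasible(u, 999))
  expect_true(battery_feasible(u, 1000))
  expect_false(battery_feasible(list(battery_level = 10,
                                     battery_consumption_rate = 0.1), 101))
})

test_that("enumerate_paths builds the full user x AED x emergency grid", {
  scn <- generate_scenario(4, 3, 2, seed = 3)
  ps <- enumerate_paths(scn)
  expect_equal(nrow(ps$paths), 24L)

  # n' x m' x o counts only available users and functional AEDs
  scn$users$available[1] <- FALSE
  scn$aeds$functional[2] <- FALSE
  ps2 <- enumerate_paths(rns_scenario(scn$users, scn$aeds, scn$emergencies))
  expect_equal(nrow(ps2$paths), 3L * 2L * 2L)
  expect_false(any(ps2$paths$user_id == scn$users$id[1]))
  expect_false(any(ps2$paths$aed_id == scn$aeds$id[2]))

  # empty factors give empty path sets
  ps0 <- enumerate_paths(rns_scenario(scn$users, scn$aeds, NULL))
  expect_equal(nrow(ps0$paths), 0L)
})

test_that("path set invariants hold over random sizes (property)", {
  for (seed in 1:12) {
    n <- (seed * 7) %% 6 + 1; m <- (seed * 5) %% 4 + 1; o <- seed %% 3 + 1
    ps <- enumerate_paths(small_instance(n, m, o, seed))
    expect_equal(nrow(ps$paths), n * m * o)
    # sentinel strictly exceeds every real travel time
    expect_true(all(ps$paths$travel_time < ps$max_edge_weight))
    expect_equal(ps$max_edge_weight, max(ps$paths$travel_time) + 1)
    # time = distance / speed, and feasibility is the powered-time test
    scn <- small_instance(n, m, o, seed)
    sp <- scn$users$walking_speed[match(ps$paths$user_id, scn$users$id)]
    expect_equal(ps$paths$travel_time, ps$paths$travel_distance / sp)
    pw <- with(scn$users, battery_level / battery_consumption_rate)
    pw <- pw[match(ps$paths$user_id, scn$users$id)]
    expect_equal(ps$paths$battery_feasible, pw >= ps$paths$travel_time)
  }
})

test_that("travel time is monotone in walking speed; battery in trip length", {
  u <- list(id = "u", x = 0, y = 0, walking_speed = 1.0,
            battery_level = 30, battery_consumption_rate = 0.01)
  a <- list(id = "a", x = 80, y = 60); e <- list(id = "e", x = 10, y = 10)
  t_slow <- travel_time(u, a, e)
  t_fast <- travel_time(modifyList(u, list(walking_speed = 1.5)), a, e)
  expect_true(t_fast < t_slow)
  # infeasible at t implies infeasible at any longer t
  tt <- powered_time(u)
  expect_false(battery_feasible(u, tt + 1))
  expect_false(battery_feasible(u, tt + 100))
})

test_that("radius selection keeps the straight-line fallacy visible", {
  users <- data.frame(
    id = c("near", "far", "around_the_block"),
    x = c(499, 501, 100), y = 0,
    walking_speed = 1, battery_level = 100,
    battery_consumption_rate = 0.01, available = TRUE)
  emergency <- list(id = "e1", x = 0, y = 0)
  sel <- radius_select(users, emergency, radius = 500)
  expect_setequal(sel$id, c("near", "around_the_block"))
  # the 100 m straight-line user is selected even if their walking route
  # (say 600 m via a tabulated matrix) exceeds the 500 m threshold --
  # that is the documented flaw of the legacy radius rule
  expect_true("around_the_block" %in% sel$id)
  expect_equal(nrow(radius_select(users[0, ], emergency, 500)), 0L)
})
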