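# cost-matrix construction, Hungarian assignment, post-filtering, iteration

test_that("cost matrix combines AEDs and emergencies and pads square", {
  # 3 users x (2 AEDs x 2 emergencies) -> 4 columns, 1 dummy row
  ps <- enumerate_paths(tiny_scenario())
  cm <- build_cost_matrix(ps)
  expect_equal(dim(cm), c(4L, 4L))
  expect_equal(sum(startsWith(rownames(cm), ".dummy")), 1L)
  expect_equal(colnames(cm),
               c("a1|e1", "a1|e2", "a2|e1", "a2|e2"))
  expect_true(all(cm[".dummy1", ] == ps$max_edge_weight))

  # 2 users x 1 AED x 1 emergency -> dummy column instead
  scn <- tiny_scenario()
  scn2 <- rns_scenario(scn$users[1:2, ], scn$aeds[1, , drop = FALSE],
                       scn$emergencies[1, , drop = FALSE])
  cm2 <- build_cost_matrix(enumerate_paths(scn2))
  expect_equal(dim(cm2), c(2L, 2L))
  expect_equal(sum(startsWith(colnames(cm2), ".dummy")), 1L)
})

test_that("battery-infeasible cells are sentineled; hopeless users dropped", {
  scn <- tiny_scenario(battery_level = c(100, 100, 1e-6), rate = 0.01)
  ps <- enumerate_paths(scn)
  cm <- build_cost_matrix(ps)
  # u3 has no feasible path at all -> row dropped entirely
  expect_false("u3" %in% rownames(cm))
  # per-cell: a 200 s power budget cuts u1's two 250 s paths only
  scn2 <- tiny_scenario(battery_level = c(2, 100, 100), rate = 0.01)
  ps2 <- enumerate_paths(scn2)
  cm2 <- build_cost_matrix(ps2)
  infeas <- ps2$paths[ps2$paths$user_id == "u1" & !ps2$paths$battery_feasible, ]
  expect_gt(nrow(infeas), 0L)
  for (i in seq_len(nrow(infeas))) {
    expect_equal(cm2["u1", paste(infeas$aed_id[i], infeas$emergency_id[i],
                                 sep = "|")],
                 ps2$max_edge_weight)
  }
  # all paths infeasible -> empty-result signal, not an exception
  expect_null(build_cost_matrix(enumerate_paths(
    tiny_scenario(battery_level = 0.000001, rate = 1))))
})

test_that("hungarian assignment matches the exhaustive permutation optimum", {
  m <- matrix(c(1, 2, 2, 1), 2, 2, byrow = TRUE)
  a <- hungarian_assign(m)
  expect_equal(sum(a$cost), 2)
  expect_equal(a$col, c(1L, 2L))

  m2 <- matrix(c(0, 9, 9, 0), 2, 2, byrow = TRUE)
  expect_equal(hungarian_assign(m2)$col, c(1L, 2L))

  # random 3x3 and 4x4 integer matrices vs brute-force over permutations
  set.seed(99)
  for (rep in 1:20) {
    k <- sample(3:4, 1)
    m3 <- matrix(sample.int(50, k * k, replace = TRUE), k, k)
    best <- min(vapply(
      asplit(as.matrix(expand.grid(rep(list(seq_len(k)), k))), 1),
      function(p) if (anyDuplicated(p)) Inf else sum(m3[cbind(seq_len(k), p)]),
      numeric(1)))
    expect_equal(sum(hungarian_assign(m3)$cost), best)
  }
})

test_that("post-filtering drops sentinels and keeps the faster duplicate", {
  ps <- enumerate_paths(tiny_scenario())
  cm <- build_cost_matrix(ps)
  mew <- ps$max_edge_weight
  # force an assignment by hand: u1 -> a1|e1, u2 -> a1|e2 duplicates AED a1
  asg <- data.frame(row = c(1L, 2L, 3L, 4L),
                    col = c(match("a1|e1", colnames(cm)),
                            match("a1|e2", colnames(cm)),
                            match("a2|e1", colnames(cm)),
                            match("a2|e2", colnames(cm))))
  asg$cost <- c(100, 80, 120, mew)
  res <- postprocess_assignment(asg, cm, new_match_set(), mew)
  m <- res$match_set$matches
  # sentinel pair gone; of the two a1 pairs the 80 s one survives
  expect_equal(anyDuplicated(m$aed_id), 0L)
  expect_true(all(m$travel_time < mew))
  expect_equal(m$travel_time[m$aed_id == "a1"], 80)
  # a pre-existing faster match on the same user wins over a new slower one
  cur <- new_match_set(data.frame(user_id = "u1", aed_id = "a2",
                                  emergency_id = "e1", travel_time = 10))
  res2 <- postprocess_assignment(asg[1, ], cm, cur, mew)
  expect_equal(res2$accepted, 0L)
  expect_equal(res2$match_set$matches$travel_time, 10)
})

test_that("iterative matching terminates with valid AED-limited output", {
  scn <- tiny_scenario()
  ps <- enumerate_paths(scn)
  ms <- match_bipartite(scn)
  expect_valid_match_set(ms, ps)
  expect_equal(nrow(ms$matches), 2L)     # limited by the two AEDs

  # single forced option
  s1 <- rns_scenario(scn$users[1, , drop = FALSE],
                     scn$aeds[1, , drop = FALSE],
                     scn$emergencies[1, , drop = FALSE])
  expect_equal(nrow(match_bipartite(s1)$matches), 1L)

  # everything battery-infeasible -> empty result
  dead <- tiny_scenario(battery_level = 1e-9, rate = 1)
  expect_equal(nrow(match_bipartite(dead)$matches), 0L)

  # empty scenario -> empty result
  empty <- rns_scenario(NULL, NULL, NULL)
  expect_equal(nrow(match_bipartite(empty)$matches), 0L)
})

test_that("on single-emergency instances the iteration reaches the optimum", {
  # with one emergency the bipartite solve is the assignment problem itself,
  # so its total must equal the exhaustive-oracle total at full cardinality
  for (seed in c(11, 12, 13, 14)) {
    scn <- small_instance(5, 3, 1, seed)
    ps <- enumerate_paths(scn)
    bm <- match_bipartite(scn)
    bf <- brute_force_match(ps)
    expect_valid_match_set(bm, ps)
    expect_equal(nrow(bm$matches), nrow(bf$matches))
    expect_equal(bm$total_match_time, bf$total_match_time, tolerance = 1e-9)
  }
})
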