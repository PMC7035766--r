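test_that("the ranked space contains ranked vectors and excludes ties", {
  s <- weight_space(c("c1", "c2", "c3", "c4"))
  expect_true(in_space(s, c(c1 = 0.4, c2 = 0.3, c3 = 0.2, c4 = 0.1)))
  expect_false(in_space(s, c(c1 = 0.25, c2 = 0.25, c3 = 0.25, c4 = 0.25)))
  expect_true(is_feasible(s))
  expect_error(weight_space(c("c1", "c1")), "duplicate")
})

test_that("two-criterion geometry: k2 is at most one half", {
  s <- weight_space(c("c1", "c2"), delta = 0)
  b <- weight_bounds(s)
  expect_equal(b$upper[b$criterion == "c2"], 0.5, tolerance = 1e-9)
  expect_equal(b$upper[b$criterion == "c1"], 1, tolerance = 1e-9)
  expect_equal(b$lower[b$criterion == "c1"], 0.5, tolerance = 1e-9)
})

test_that("ranking-only bounds match simplex geometry for four criteria", {
  s <- weight_space(paste0("c", 1:4), delta = 0)
  b <- weight_bounds(s)
  expect_equal(b$upper, c(1, 0.5, 1 / 3, 0.25), tolerance = 1e-9)
  expect_equal(b$lower, c(0.25, 0, 0, 0), tolerance = 1e-9)
})

test_that("a B-answer strictly lowers the top criterion's maximum weight", {
  s <- weight_space(c("c1", "c2"))
  before <- weight_bounds(s)
  s2 <- add_statement(s, tradeoff_statement("c1", "c2", 0.5, "B"))
  after <- weight_bounds(s2)
  expect_lt(after$upper[1], before$upper[1])
  # k2 >= 0.5 k1 and k1 + k2 = 1 give k1 <= 2/3
  expect_equal(after$upper[1], 2 / 3, tolerance = 1e-4)
})

test_that("an A-answer at a level near 1 barely changes the space", {
  s <- weight_space(c("c1", "c2"))
  before <- weight_bounds(s)
  s2 <- add_statement(s, tradeoff_statement("c1", "c2", 0.999, "A"))
  after <- weight_bounds(s2)
  expect_equal(after$upper, before$upper, tolerance = 1e-2)
  expect_equal(after$lower, before$lower, tolerance = 1e-2)
})

test_that("contradictory answers at the same level are rejected as inconsistent", {
  s <- weight_space(c("c1", "c2"))
  s2 <- add_statement(s, tradeoff_statement("c1", "c2", 0.5, "A"))
  expect_error(
    add_statement(s2, tradeoff_statement("c1", "c2", 0.5, "B")),
    class = "fitradeoff_inconsistent"
  )
})

test_that("LP maxima equal ranked-vertex enumeration exactly at delta = 0", {
  p <- triage_problem()
  rk <- triage_ranking()
  s <- weight_space(rk, delta = 0)
  mv <- max_additive_value(s, p)
  for (a in p$alternatives) {
    expect_equal(mv$max_value[mv$alternative == a],
                 vertex_max_value(p, rk, a), tolerance = 1e-9)
  }
  set.seed(99)
  for (rep in 1:10) {
    p <- generate_problem(synthetic_spec())
    s <- weight_space(p$criteria, delta = 0)
    mv <- max_additive_value(s, p)
    for (a in p$alternatives) {
      expect_equal(mv$max_value[mv$alternative == a],
                   vertex_max_value(p, p$criteria, a), tolerance = 1e-9)
    }
  }
})

test_that("LP argmax weights satisfy the simplex and all stored constraints", {
  set.seed(12)
  p <- generate_problem(synthetic_spec())
  s <- weight_space(p$criteria)
  s <- add_statement(s, tradeoff_statement("c1", "c3", 0.6, "B"))
  mv <- max_additive_value(s, p)
  for (k in mv$weights) {
    expect_equal(sum(k), 1, tolerance = 1e-6)
    expect_true(in_space(s, k, tol = 1e-6))
  }
})

test_that("weight bounds and survivor sets nest as statements accumulate", {
  set.seed(4821)
  for (rep in 1:10) {
    p <- generate_problem(synthetic_spec())
    s <- weight_space(p$criteria)
    b <- weight_bounds(s)
    surv <- survivors(filter_potentially_optimal(s, p))
    for (step in 1:3) {
      stmt <- random_statement(s)
      if (is.null(stmt)) break
      s2 <- tryCatch(add_statement(s, stmt),
                     fitradeoff_inconsistent = function(e) NULL)
      if (is.null(s2)) next
      s <- s2
      b2 <- weight_bounds(s)
      expect_true(all(b2$lower >= b$lower - 1e-7))
      expect_true(all(b2$upper <= b$upper + 1e-7))
      surv2 <- survivors(filter_potentially_optimal(s, p))
      expect_true(all(surv2 %in% surv))
      mv <- max_additive_value(s, p)
      expect_true(all(mv$max_value <= 1 + 1e-9 & mv$max_value >= -1e-9))
      b <- b2
      surv <- surv2
    }
  }
})

test_that("ratio bounds report the feasible interval of a pair's weight ratio", {
  s <- weight_space(c("c1", "c2"), delta = 0)
  rb <- ratio_bounds(s, "c1", "c2")
  expect_equal(unname(rb), c(0, 1), tolerance = 1e-6)
  s2 <- add_statement(s, tradeoff_statement("c1", "c2", 0.5, "B"))
  rb2 <- ratio_bounds(s2, "c1", "c2")
  expect_equal(unname(rb2["lower"]), 0.5, tolerance = 1e-4)
  expect_equal(unname(rb2["upper"]), 1, tolerance = 1e-6)
  expect_error(ratio_bounds(s, "c2", "c1"), "ranked above")
})

test_that("statements may connect non-adjacent ranks", {
  s <- weight_space(paste0("c", 1:4))
  s2 <- add_statement(s, tradeoff_statement("c1", "c4", 0.5, "B"))
  b <- weight_bounds(s2)
  # k4 >= 0.5 k1 forces a floor on the bottom weight
  expect_gt(b$lower[b$criterion == "c4"], 0.1)
  expect_true(is_feasible(s2))
})
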