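test_that("bisection starts at the ratio midpoint and halves after an answer", {
  s <- weight_space(c("c1", "c2"), delta = 0)
  q1 <- next_question(s)
  expect_equal(q1$higher, "c1")
  expect_equal(q1$lower, "c2")
  expect_equal(q1$level, 0.5, tolerance = 1e-6)
  s2 <- add_statement(s, tradeoff_statement(q1$higher, q1$lower, q1$level, "A"))
  q2 <- next_question(s2)
  expect_equal(q2$level, 0.25, tolerance = 1e-4)
  s3 <- add_statement(s, tradeoff_statement(q1$higher, q1$lower, q1$level, "B"))
  q3 <- next_question(s3)
  expect_equal(q3$level, 0.75, tolerance = 1e-4)
})

test_that("question levels stay strictly inside (0, 1)", {
  expect_error(tradeoff_question("c1", "c2", 0), "in \\(0, 1\\)")
  expect_error(tradeoff_question("c1", "c2", 1), "in \\(0, 1\\)")
  s <- weight_space(paste0("c", 1:3))
  q <- next_question(s)
  expect_true(q$level > 0 && q$level < 1)
})

test_that("a simulated decision maker answers from its hidden weights", {
  dm <- simulated_dm(c(c1 = 0.6, c2 = 0.4), band = 0)
  expect_equal(dm$answer(tradeoff_question("c1", "c2", 0.5)), "B")   # 0.30 < 0.40
  expect_equal(dm$answer(tradeoff_question("c1", "c2", 0.9)), "A")   # 0.54 > 0.40
  dm_band <- simulated_dm(c(c1 = 0.6, c2 = 0.4), band = 0.01)
  expect_equal(dm_band$answer(tradeoff_question("c1", "c2", 0.4 / 0.6)),
               "indifferent")
})

test_that("an exhausted answer script falls back to the LP-value tie-break", {
  p <- triage_problem()
  empty <- scripted_answers(tibble::tibble(higher = character(),
                                           lower = character(),
                                           answer = character()))
  sess <- run_session(p, triage_ranking(), empty)
  expect_equal(sess$termination, "answers_exhausted")
  expect_equal(sess$n_questions, 0)
  # recommendation = survivor with the greatest ranked-space LP maximum (ATS: 1)
  expect_equal(sess$recommendation, "ATS")
})

test_that("replaying the same script reproduces the same session", {
  p <- triage_problem()
  a <- run_session(p, triage_ranking(), scripted_answers(triage_answer_script()))
  b <- run_session(p, triage_ranking(), scripted_answers(triage_answer_script()))
  expect_equal(a$recommendation, b$recommendation)
  expect_equal(a$log$level, b$log$level)
  expect_equal(a$log$n_survivors, b$log$n_survivors)
})

test_that("survivor counts never increase along a session log", {
  p <- triage_problem()
  sess <- run_session(p, triage_ranking(),
                      scripted_answers(triage_answer_script()))
  expect_true(all(diff(sess$log$n_survivors) <= 0))
  w <- final_solution_weights()
  sess2 <- run_session(p, triage_ranking(), simulated_dm(w / sum(w)))
  expect_true(all(diff(sess2$log$n_survivors) <= 0))
})

test_that("a consistent decision maker's true best is never eliminated", {
  set.seed(202)
  for (rep in 1:5) {
    p <- generate_problem(synthetic_spec())
    w <- setNames(draw_true_weights(4), p$criteria)
    truth <- additive_value(p, w)
    best <- truth$alternative[which.max(truth$value)]
    sess <- run_session(p, p$criteria, simulated_dm(w, band = 0))
    for (surv in sess$log$survivors) expect_true(best %in% surv)
    expect_equal(sess$recommendation, best)
  }
})

test_that("a decision maker may stop early and get the current best survivor", {
  p <- triage_problem()
  stopper <- scripted_answers(tibble::tibble(
    higher = "Guidelines", lower = "Ease of Use", answer = "stop"))
  sess <- run_session(p, triage_ranking(), stopper)
  expect_equal(sess$termination, "stopped_by_dm")
  expect_equal(sess$recommendation, "ATS")
})

test_that("inconsistent scripted answers surface as an error with the log", {
  p <- triage_problem()
  # indifference pins the pair's weight ratio; strictly preferring the
  # hypothetical at that same (bisected) level immediately after contradicts it
  bad <- triage_answer_script()[c(1, 1), ]
  bad$answer <- c("indifferent", "A")
  err <- tryCatch(
    run_session(p, triage_ranking(), scripted_answers(bad), band = 0),
    fitradeoff_inconsistent = function(e) e
  )
  expect_s3_class(err, "fitradeoff_inconsistent")
  expect_s3_class(err$session_log, "data.frame")
})

test_that("the question cap terminates a session", {
  p <- triage_problem()
  w <- final_solution_weights()
  sess <- run_session(p, triage_ranking(), simulated_dm(w / sum(w)),
                      max_questions = 2)
  expect_equal(sess$termination, "max_questions")
  expect_equal(sess$n_questions, 2)
  expect_true(sess$recommendation %in% survivors(sess))
})
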