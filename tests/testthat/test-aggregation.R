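test_that("validation prunes a 29-leaf tree to the final 27-leaf, 4-criterion tree", {
  final <- triage_criteria_tree()
  # the two subcriteria dropped at validation are unnamed in the study record;
  # synthetic placeholders stand in for them
  pre <- criteria_tree(dplyr::bind_rows(
    tibble::as_tibble(final),
    tibble::tibble(criterion = c("Guidelines", "Ease of Use"),
                   subcriterion = c("synthetic dropped leaf 1",
                                    "synthetic dropped leaf 2"))
  ))
  expect_equal(glance(pre)$n_subcriteria, 29)
  pruned <- validate_tree(pre, final$subcriterion)
  expect_equal(glance(pruned)$n_criteria, 4)
  expect_equal(glance(pruned)$n_subcriteria, 27)
  expect_setequal(pruned$subcriterion, final$subcriterion)
})

test_that("tree validation handles identity, whole-criterion drops, and bad ids", {
  tree <- triage_criteria_tree()
  expect_equal(validate_tree(tree, tree$subcriterion), tree)
  keep <- tree$subcriterion[tree$criterion != "Ease of Implementation"]
  pruned <- validate_tree(tree, keep)
  expect_false("Ease of Implementation" %in% pruned$criterion)
  expect_equal(glance(pruned)$n_criteria, 3)
  expect_error(validate_tree(tree, "no such leaf"), "not in the tree")
  dup <- tibble::tibble(criterion = c("a", "b"), subcriterion = c("s", "s"))
  expect_error(criteria_tree(dup), "unique")
})

test_that("Likert aggregation is the arithmetic mean per subcriterion", {
  resp <- tibble::tibble(
    respondent = rep(1:20, 2),
    subcriterion = rep(c("Adult", "Unanimous"), each = 20),
    score = c(rep(5, 18), 4, 4, rep(5, 20))
  )
  agg <- aggregate_likert_mean(resp)
  # 18 fives and two fours sum to 98 over 20 respondents -> 4.90
  expect_equal(agg$mean_score[agg$subcriterion == "Adult"], 4.90)
  expect_equal(agg$mean_score[agg$subcriterion == "Unanimous"], 5)
  expect_equal(agg$n_respondents, c(20L, 20L))
  single <- aggregate_likert_mean(
    tibble::tibble(respondent = 1, subcriterion = "s", score = 3))
  expect_equal(single$mean_score, 3)
})

test_that("Likert aggregation is respondent-permutation invariant and validates", {
  set.seed(7)
  resp <- tibble::tibble(
    respondent = rep(1:10, 3),
    subcriterion = rep(c("a", "b", "c"), each = 10),
    score = sample(1:5, 30, replace = TRUE)
  )
  shuffled <- resp[sample(nrow(resp)), ]
  expect_equal(aggregate_likert_mean(resp), aggregate_likert_mean(shuffled))
  expect_error(aggregate_likert_mean(resp[0, ]), "empty")
  bad <- resp
  bad$score[1] <- 6
  expect_error(aggregate_likert_mean(bad), "scale")
})

test_that("specialist aggregation equals an independently coded accumulation loop", {
  set.seed(31)
  tree <- triage_criteria_tree()
  for (rep in 1:5) {
    scores <- tidyr::expand_grid(
      alternative = c("P1", "P2", "P3"),
      subcriterion = tree$subcriterion
    )
    scores$score <- sample(0:5, nrow(scores), replace = TRUE)
    got <- aggregate_specialist_sum(scores, tree)
    # oracle: plain accumulation loop over rows
    acc <- list()
    for (r in seq_len(nrow(scores))) {
      crit <- tree$criterion[tree$subcriterion == scores$subcriterion[r]]
      key <- paste(scores$alternative[r], crit, sep = "\r")
      acc[[key]] <- (acc[[key]] %||% 0) + scores$score[r]
    }
    for (r in seq_len(nrow(got))) {
      key <- paste(got$alternative[r], got$criterion[r], sep = "\r")
      expect_equal(got$score[r], acc[[key]])
    }
    # every entry within [0, 5 * leaves under the criterion]
    leaves <- table(tree$criterion)
    expect_true(all(got$score >= 0 &
                      got$score <= 5 * as.numeric(leaves[got$criterion])))
  }
})

test_that("specialist aggregation handles zero matrices and missing cells", {
  tree <- triage_criteria_tree()
  zero <- tidyr::expand_grid(alternative = c("P1", "P2"),
                             subcriterion = tree$subcriterion)
  zero$score <- 0
  agg <- aggregate_specialist_sum(zero, tree)
  expect_true(all(agg$score == 0))
  expect_equal(nrow(agg), 2 * 4)
  expect_error(aggregate_specialist_sum(zero[-1, ], tree), "missing")
})

test_that("a weighted-sum hook is available but defaults to the plain sum", {
  tree <- criteria_tree(tibble::tibble(criterion = c("c", "c"),
                                       subcriterion = c("s1", "s2")))
  scores <- tibble::tibble(alternative = c("a", "a"),
                           subcriterion = c("s1", "s2"), score = c(2, 4))
  expect_equal(aggregate_specialist_sum(scores, tree)$score, 6)
  w <- c(s1 = 1, s2 = 0.25)
  expect_equal(aggregate_specialist_sum(scores, tree, subweights = w)$score, 3)
  expect_error(aggregate_specialist_sum(scores, tree, subweights = c(s1 = 1)),
               "cover")
})
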