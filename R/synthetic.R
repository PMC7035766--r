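#' Specification of a synthetic decision problem
#'
#' Describes the random problems used to exercise the pipeline end-to-end:
#' integer raw scores drawn uniformly per cell (mimicking summed
#' questionnaire points), and a hidden true scale-constant vector drawn
#' uniformly from the ranked simplex (or fixed by the user) that a simulated
#' decision maker answers from.
#'
#' @param n_alternatives,n_criteria Problem dimensions (both at least 2).
#' @param score_range Integer raw-score range, default `c(0, 30)`.
#' @param true_weights Optional fixed true scale constants (descending,
#'   non-negative, summing to 1); if `NULL`, drawn per replicate.
#' @param band Half-width of the simulated decision maker's indifference
#'   band on the 0-1 value scale (default 0: always decisive).
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_alternatives = 5, n_criteria = 4,
                           score_range = c(0, 30), true_weights = NULL,
                           band = 0) {
  stopifnot(n_alternatives >= 2, n_criteria >= 2,
            length(score_range) == 2, score_range[1] <= score_range[2],
            band >= 0)
  if (!is.null(true_weights)) {
    stopifnot(length(true_weights) == n_criteria)
    if (any(diff(unname(true_weights)) > 0)) {
      rlang::abort("true_weights must respect the ranking (non-increasing)")
    }
    if (any(true_weights < 0) || abs(sum(true_weights) - 1) > 1e-9) {
      rlang::abort("true_weights must be non-negative and sum to 1")
    }
  }
  structure(
    list(n_alternatives = as.integer(n_alternatives),
         n_criteria = as.integer(n_criteria),
         score_range = as.integer(score_range),
         true_weights = true_weights,
         band = band),
    class = "synthetic_spec"
  )
}

#' Generate a random decision problem
#'
#' Raw scores are integers drawn uniformly in the spec's range; constant
#' columns are redrawn so every criterion is non-degenerate.  Alternatives
#' are labelled `a01, a02, ...` and criteria `c1, c2, ...` with `c1` the
#' top-ranked criterion.
#'
#' @param spec A [synthetic_spec()].
#' @param seed Optional integer seed for reproducibility.
#' @return A [decision_problem()].
#' @export
generate_problem <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (!is.null(seed)) set.seed(seed)
  lo <- spec$score_range[1]
  hi <- spec$score_range[2]
  if (lo == hi && spec$n_alternatives > 1) {
    rlang::abort("score range of width 0 cannot produce non-degenerate columns")
  }
  na <- spec$n_alternatives
  nc <- spec$n_criteria
  m <- matrix(sample(lo:hi, na * nc, replace = TRUE), na, nc)
  for (j in seq_len(nc)) {
    tries <- 0L
    while (max(m[, j]) == min(m[, j])) {
      m[, j] <- sample(lo:hi, na, replace = TRUE)
      tries <- tries + 1L
      if (tries > 1000L) rlang::abort("could not draw a non-degenerate column")
    }
  }
  dimnames(m) <- list(sprintf("a%02d", seq_len(na)), paste0("c", seq_len(nc)))
  new_decision_problem(m)
}

#' Draw true scale constants uniformly from the ranked simplex
#'
#' Draws a flat Dirichlet sample and sorts it in decreasing order, which is
#' uniform over the region of the simplex respecting the ranking.
#'
#' @param n_criteria Number of criteria.
#' @return Descending numeric vector summing to 1.
#' @export
draw_true_weights <- function(n_criteria) {
  g <- stats::rexp(n_criteria)
  sort(g / sum(g), decreasing = TRUE)
}

#' Simulated decision maker
#'
#' Answers tradeoff questions consistently with a hidden true scale-constant
#' vector: for a question at level `v` on pair (i, j) it compares
#' `k_i * v` with `k_j` and answers `"A"` when the hypothetical wins by more
#' than `band`, `"B"` when it loses by more than `band`, and
#' `"indifferent"` otherwise.
#'
#' @param true_weights Named numeric vector of true scale constants.
#' @param band Indifference half-width (default 0).
#' @return An `answer_source` for [run_session()].
#' @export
simulated_dm <- function(true_weights, band = 0) {
  stopifnot(is.numeric(true_weights), !is.null(names(true_weights)), band >= 0)
  structure(
    list(
      kind = "simulated",
      true_weights = true_weights,
      band = band,
      has_next = function() TRUE,
      next_pair = function() NULL,
      answer = function(question) {
        ki <- true_weights[[question$higher]]
        kj <- true_weights[[question$lower]]
        lhs <- ki * question$level
        if (lhs > kj + band) "A"
        else if (lhs < kj - band) "B"
        else "indifferent"
      }
    ),
    class = "answer_source"
  )
}

#' Weight-recovery experiment for the elicitation loop
#'
#' For each replicate: generate a random problem, draw (or reuse) true scale
#' constants, run a full elicitation session against the simulated decision
#' maker, and record whether the recommendation equals the alternative that
#' is truly best under the hidden weights.
#'
#' @param spec A [synthetic_spec()].
#' @param n_replicates Number of replicates (at least 1).
#' @param seed Integer seed driving all randomness.
#' @param max_questions Question cap per session.
#' @param delta,band_space Weight-space strictness and indifference band.
#' @return A tibble of class `recovery_experiment` with one row per
#'   replicate: `replicate`, `recommended`, `true_best`, `recovered`,
#'   `n_questions`, `termination`, `margin` (true-value gap between the best
#'   and second-best alternative).  `glance()` summarises the recovery
#'   fraction and mean question count.
#' @export
recovery_experiment <- function(spec, n_replicates, seed = NULL,
                                max_questions = 50L, delta = 1e-6,
                                band_space = 1e-6) {
  stopifnot(inherits(spec, "synthetic_spec"), n_replicates >= 1)
  if (!is.null(seed)) set.seed(seed)
  rows <- purrr::map(seq_len(n_replicates), function(r) {
    problem <- generate_problem(spec)
    crits <- problem$criteria
    w <- spec$true_weights %||% draw_true_weights(spec$n_criteria)
    w <- stats::setNames(unname(w), crits)   # descending: ranking = c1 > c2 > ...
    truth <- additive_value(problem, w)
    truth <- truth[order(-truth$value, truth$alternative), ]
    margin <- truth$value[1] - truth$value[2]
    sess <- run_session(problem, ranking = crits,
                        answers = simulated_dm(w, band = spec$band),
                        delta = delta, band = band_space,
                        max_questions = max_questions)
    tibble::tibble(
      replicate = r,
      recommended = sess$recommendation,
      true_best = truth$alternative[1],
      recovered = sess$recommendation == truth$alternative[1],
      n_questions = sess$n_questions,
      termination = sess$termination,
      margin = margin
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("recovery_experiment", class(out))
  attr(out, "spec") <- spec
  out
}

#' @export
glance.recovery_experiment <- function(x, ...) {
  tibble::tibble(
    n_replicates = nrow(x),
    recovery_fraction = mean(x$recovered),
    mean_questions = mean(x$n_questions),
    mean_margin = mean(x$margin)
  )
}
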