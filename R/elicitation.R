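#' A tradeoff question
#'
#' Asks the decision maker to compare two hypothetical consequences:
#' consequence A scores `level` (on the normalized 0-1 value scale) on the
#' higher-ranked criterion and worst on all others; consequence B scores best
#' on the lower-ranked criterion and worst on all others.
#'
#' @param higher,lower Criterion ids, `higher` ranked above `lower`.
#' @param level Normalized value of the hypothetical level, in (0, 1).
#' @return An object of class `tradeoff_question`.
#' @export
tradeoff_question <- function(higher, lower, level) {
  if (!(level > 0 && level < 1)) {
    rlang::abort("question level must be in (0, 1)")
  }
  structure(list(higher = higher, lower = lower, level = level),
            class = "tradeoff_question")
}

#' @export
format.tradeoff_question <- function(x, ...) {
  paste0(
    "Which do you prefer?\n",
    "  A: '", x$higher, "' at ", round(100 * x$level), "% of its best value, ",
    "worst on all other criteria\n",
    "  B: '", x$lower, "' at its best value, worst on all other criteria"
  )
}

#' @export
print.tradeoff_question <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Choose the next tradeoff question
#'
#' The default `"bisection"` strategy inspects every ranked criterion pair
#' (i above j), computes the feasible interval of the weight ratio
#' \eqn{k_j/k_i} via [ratio_bounds()], picks the pair with the widest
#' interval, and places the hypothetical level at the interval midpoint, so
#' each answer halves the remaining ratio uncertainty on that pair.
#' Deterministic for a given space (ties broken by rank order).
#'
#' @param space A feasible [weight_space()].
#' @param problem Unused by the bisection strategy; reserved for
#'   problem-aware strategies.
#' @param strategy Question-selection strategy; only `"bisection"`.
#' @param pair Optional character vector `c(higher, lower)` forcing the
#'   criterion pair (used when replaying a recorded session); the level is
#'   still the bisection midpoint for that pair.
#' @param level_clip Levels are clipped into
#'   `[level_clip, 1 - level_clip]` so the hypothetical stays strictly
#'   between worst and best.
#' @return A [tradeoff_question()].
#' @export
next_question <- function(space, problem = NULL, strategy = "bisection",
                          pair = NULL, level_clip = 1e-3) {
  stopifnot(inherits(space, "weight_space"))
  strategy <- match.arg(strategy, "bisection")
  rk <- space$ranking
  n <- length(rk)
  if (is.null(pair)) {
    pairs <- list()
    for (i in seq_len(n - 1)) {
      for (j in seq((i + 1), n)) {
        pairs[[length(pairs) + 1L]] <- c(rk[i], rk[j])
      }
    }
    ints <- purrr::map(pairs, ~ ratio_bounds(space, .x[1], .x[2]))
    widths <- purrr::map_dbl(ints, ~ .x["upper"] - .x["lower"])
    best <- which.max(widths)   # first widest wins: deterministic tie-break
    pair <- pairs[[best]]
    int <- ints[[best]]
  } else {
    stopifnot(length(pair) == 2)
    int <- ratio_bounds(space, pair[1], pair[2])
  }
  level <- (int["lower"] + int["upper"]) / 2
  level <- min(max(level, level_clip), 1 - level_clip)
  tradeoff_question(pair[1], pair[2], unname(level))
}

#' Scripted answer source
#'
#' Replays a recorded elicitation session: each entry fixes the criterion
#' pair of the question and the decision maker's answer; the hypothetical
#' level is chosen by the session's bisection strategy at ask time.
#'
#' @param script A data frame with columns `higher`, `lower`, `answer`
#'   (answers in `"A"`, `"B"`, `"indifferent"`), or a path to a JSON file
#'   holding such records.
#' @return An `answer_source` for [run_session()].
#' @export
scripted_answers <- function(script) {
  if (is.character(script) && length(script) == 1) {
    script <- tibble::as_tibble(jsonlite::fromJSON(script))
  }
  stopifnot(is.data.frame(script))
  needed <- c("higher", "lower", "answer")
  if (!all(needed %in% names(script))) {
    rlang::abort("script needs columns higher, lower, answer")
  }
  bad <- setdiff(unique(script$answer), c("A", "B", "indifferent", "stop"))
  if (length(bad) > 0) {
    rlang::abort(paste0("unknown answers in script: ", paste(bad, collapse = ", ")))
  }
  pos <- 0L
  env <- environment()
  structure(
    list(
      kind = "scripted",
      has_next = function() pos < nrow(script),
      next_pair = function() {
        c(script$higher[pos + 1L], script$lower[pos + 1L])
      },
      answer = function(question) {
        env$pos <- pos + 1L
        script$answer[pos]
      }
    ),
    class = "answer_source"
  )
}

#' Answer source reading from the console
#'
#' Prompts interactively for `A`, `B`, `i` (indifferent) or `q` (stop and
#' recommend from the current survivors).
#'
#' @return An `answer_source` for [run_session()].
#' @export
interactive_answers <- function() {
  structure(
    list(
      kind = "interactive",
      has_next = function() interactive(),
      next_pair = function() NULL,
      answer = function(question) {
        cat(format(question), "\n")
        repeat {
          ans <- tolower(trimws(readline("answer [A/B/i/q]: ")))
          if (ans %in% c("a", "b")) return(toupper(ans))
          if (ans %in% c("i", "indifferent")) return("indifferent")
          if (ans %in% c("q", "quit", "stop")) return("stop")
        }
      }
    ),
    class = "answer_source"
  )
}

#' @export
print.answer_source <- function(x, ...) {
  cat("<answer_source> kind:", x$kind, "\n")
  invisible(x)
}

#' Run an elicitation session to a recommendation
#'
#' Drives the flexible-interactive loop: filter the alternatives down to the
#' potentially optimal set, stop if a single survivor remains (or the answer
#' source is exhausted, or `max_questions` is reached), otherwise ask the
#' next tradeoff question, shrink the weight space with the answer, and
#' repeat.  If several survivors remain at the stop, the one with the
#' greatest LP maximum value is recommended (ties broken by alphabetical
#' id).
#'
#' @param problem A [decision_problem()].
#' @param ranking Character vector of criterion ids, most important first.
#' @param answers An `answer_source` ([scripted_answers()],
#'   [simulated_dm()], [interactive_answers()]).
#' @param delta Strictness separation of the weight space.
#' @param band Indifference band half-width.
#' @param max_questions Hard cap on the number of questions.
#' @param tol Elimination tolerance, passed to the dominance filter.
#' @return An object of class `fitradeoff_session`: a list with elements
#'   `recommendation`, `termination`, `n_questions`, `log` (one row per
#'   step with the question, answer, survivor count and weight bounds),
#'   `final_space`, `final_set`, `problem`, `ranking`.
#' @export
run_session <- function(problem, ranking, answers,
                        delta = 1e-6, band = 1e-6,
                        max_questions = 50L, tol = 1e-7) {
  stopifnot(inherits(problem, "decision_problem"),
            inherits(answers, "answer_source"))
  space <- weight_space(ranking, delta = delta, band = band)
  check_same_criteria(space, problem)

  log <- list()
  record <- function(step, q, ans, set) {
    log[[length(log) + 1L]] <<- tibble::tibble(
      question_no = step,
      higher = if (is.null(q)) NA_character_ else q$higher,
      lower = if (is.null(q)) NA_character_ else q$lower,
      level = if (is.null(q)) NA_real_ else q$level,
      answer = ans %||% NA_character_,
      n_survivors = sum(set$potentially_optimal),
      survivors = list(survivors(set)),
      bounds = list(weight_bounds(space))
    )
  }

  step <- 0L
  set <- filter_potentially_optimal(space, problem, tol = tol)
  record(step, NULL, NULL, set)
  termination <- NULL
  repeat {
    if (sum(set$potentially_optimal) <= 1L) {
      termination <- "unique_survivor"
      break
    }
    if (step >= max_questions) {
      termination <- "max_questions"
      break
    }
    if (!answers$has_next()) {
      termination <- "answers_exhausted"
      break
    }
    q <- next_question(space, problem, pair = answers$next_pair())
    ans <- answers$answer(q)
    if (identical(ans, "stop")) {
      termination <- "stopped_by_dm"
      break
    }
    stmt <- tradeoff_statement(q$higher, q$lower, q$level, ans)
    space <- withCallingHandlers(
      add_statement(space, stmt),
      fitradeoff_inconsistent = function(cnd) {
        rlang::abort(
          paste0("inconsistent answer at question ", step + 1L, ": ",
                 rlang::cnd_message(cnd)),
        class = "fitradeoff_inconsistent",
        session_log = dplyr::bind_rows(log),
        parent = cnd
        )
      }
    )
    step <- step + 1L
    set <- filter_potentially_optimal(space, problem, tol = tol)
    record(step, q, ans, set)
  }

  surv <- set[set$potentially_optimal, ]
  surv <- surv[order(-surv$max_value, surv$alternative), ]
  rec <- surv$alternative[1]
  structure(
    list(
      recommendation = rec,
      termination = termination,
      n_questions = step,
      log = dplyr::bind_rows(log),
      final_space = space,
      final_set = set,
      problem = problem,
      ranking = as.character(ranking)
    ),
    class = "fitradeoff_session"
  )
}

#' @export
print.fitradeoff_session <- function(x, ...) {
  cat("<fitradeoff_session> recommendation: ", x$recommendation,
      " after ", x$n_questions, " question(s) [", x$termination, "]\n",
      sep = "")
  invisible(x)
}

#' @export
survivors.fitradeoff_session <- function(x) {
  survivors(x$final_set)
}

#' @export
tidy.fitradeoff_session <- function(x, ...) {
  x$log
}

#' @export
glance.fitradeoff_session <- function(x, ...) {
  best <- x$final_set[x$final_set$alternative == x$recommendation, ]
  tibble::tibble(
    recommendation = x$recommendation,
    n_questions = x$n_questions,
    termination = x$termination,
    n_survivors = sum(x$final_set$potentially_optimal),
    max_value = best$max_value[1]
  )
}
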