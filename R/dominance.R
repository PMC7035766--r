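#' Can an alternative be optimal somewhere in the weight space?
#'
#' An alternative is *potentially optimal* if some feasible scale-constant
#' vector makes it at least as good as every other alternative.  This is
#' decided by the slack linear program: maximize `s` subject to
#' `v(alt, k) >= v(b, k) + s` for every other alternative `b` and `k` in the
#' space.  A non-negative optimal slack certifies potential optimality (the
#' witness weights are returned); a negative optimal slack is the margin by
#' which the alternative is beaten everywhere.
#'
#' Elimination is conservative: ties at the boundary keep the alternative,
#' and an alternative is declared dominated only when the optimal slack is
#' below `-tol`.
#'
#' @param space A feasible [weight_space()].
#' @param problem A [decision_problem()] on the same criteria.
#' @param alternative An alternative id.
#' @param tol Elimination tolerance on the optimal slack (default `1e-7`).
#' @return A list with elements `potentially_optimal` (logical), `slack`
#'   (optimal slack), and `weights` (witness scale constants if potentially
#'   optimal, otherwise the argmax of the slack LP).
#' @export
is_potentially_optimal <- function(space, problem, alternative, tol = 1e-7) {
  stopifnot(inherits(space, "weight_space"), inherits(problem, "decision_problem"))
  check_same_criteria(space, problem)
  if (!alternative %in% problem$alternatives) {
    rlang::abort(paste0("unknown alternative: ", alternative))
  }
  stop_if_infeasible(space)
  others <- setdiff(problem$alternatives, alternative)
  n <- length(space$criteria)
  if (length(others) == 0) {
    k <- space_lp(space, rep(0, n))$x
    return(list(potentially_optimal = TRUE, slack = Inf,
                weights = stats::setNames(k, space$criteria)))
  }
  m <- normalized_matrix(problem)[, space$criteria, drop = FALSE]
  # variables: k_1..k_n, s+ , s-; maximize s = s+ - s-
  extra_A <- rbind(
    t(vapply(others, function(b) c(m[b, ] - m[alternative, ], 1, -1),
             numeric(n + 2))),
    c(rep(0, n), 1, 0),   # s+ <= 2
    c(rep(0, n), 0, 1)    # s- <= 2 (values differ by at most 1)
  )
  extra_b <- c(rep(0, length(others)), 2, 2)
  sol <- space_lp(space, c(rep(0, n), 1, -1), maximize = TRUE,
                  n_extra = 2L, extra_A = extra_A, extra_b = extra_b)
  if (sol$status != "optimal") {
    rlang::abort(paste0("slack LP did not solve (status ", sol$status, ")"))
  }
  list(
    potentially_optimal = sol$value >= -tol,
    slack = sol$value,
    weights = stats::setNames(sol$x[seq_len(n)], space$criteria)
  )
}

#' Filter a problem down to its potentially optimal alternatives
#'
#' Applies [is_potentially_optimal()] to every alternative and attaches each
#' survivor's maximum additive value and attaining weights (via
#' [max_additive_value()]), mirroring the "possible solutions" table a
#' decision maker is shown after ranking the criteria.
#'
#' @inheritParams is_potentially_optimal
#' @return A tibble of class `potential_optimal_set` with columns
#'   `alternative`, `potentially_optimal`, `slack`, `max_value`, `weights`
#'   (list-column of the survivors' value-maximizing scale constants), and
#'   `witness` (list-column of the slack LP argmax, at which a survivor is at
#'   least tied for best).  The weight space and problem travel along as
#'   attributes.
#' @export
filter_potentially_optimal <- function(space, problem, tol = 1e-7) {
  stopifnot(inherits(space, "weight_space"), inherits(problem, "decision_problem"))
  check_same_criteria(space, problem)
  stop_if_infeasible(space)
  checks <- purrr::map(problem$alternatives,
                       ~ is_potentially_optimal(space, problem, .x, tol = tol))
  out <- tibble::tibble(
    alternative = problem$alternatives,
    potentially_optimal = purrr::map_lgl(checks, "potentially_optimal"),
    slack = purrr::map_dbl(checks, "slack"),
    max_value = NA_real_,
    weights = purrr::map(checks, "weights"),
    witness = purrr::map(checks, "weights")
  )
  mv <- max_additive_value(space, problem,
                           alternatives = out$alternative[out$potentially_optimal])
  idx <- match(mv$alternative, out$alternative)
  out$max_value[idx] <- mv$max_value
  out$weights[idx] <- mv$weights
  class(out) <- c("potential_optimal_set", class(out))
  attr(out, "space") <- space
  attr(out, "problem") <- problem
  out
}

#' Surviving alternatives of a potential-optimal filter
#'
#' @param x A `potential_optimal_set` (from [filter_potentially_optimal()])
#'   or a `fitradeoff_session` (from [run_session()]).
#' @return Character vector of potentially optimal alternative ids.
#' @export
survivors <- function(x) {
  UseMethod("survivors")
}

#' @export
survivors.potential_optimal_set <- function(x) {
  x$alternative[x$potentially_optimal]
}

#' @export
print.potential_optimal_set <- function(x, ...) {
  cat("<potential_optimal_set> ", sum(x$potentially_optimal), " of ",
      nrow(x), " alternatives potentially optimal\n", sep = "")
  NextMethod()
}

#' @export
glance.potential_optimal_set <- function(x, ...) {
  tibble::tibble(
    n_alternatives = nrow(x),
    n_survivors = sum(x$potentially_optimal),
    best_max_value = max(x$max_value, na.rm = TRUE)
  )
}
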