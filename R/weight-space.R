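#' Weight space induced by a criteria ranking
#'
#' The space of scale-constant vectors (weights) compatible with the decision
#' maker's strict importance ranking of the criteria:
#' \eqn{k_1 > k_2 > \dots > k_n}, \eqn{\sum_i k_i = 1}, \eqn{k_i \ge 0}.
#' Tradeoff statements later shrink this space via [add_statement()].
#'
#' Strict inequalities are represented as weak inequalities with a small
#' separation `delta`, so that every linear program over the space is over a
#' closed polytope.
#'
#' @param ranking Character vector of criterion ids, most important first;
#'   must be a strict total order (no duplicates).
#' @param delta Strictness separation for `>` constraints (default `1e-6`).
#' @param band Half-width of the two-sided band used for indifference
#'   statements (default `1e-6`).
#' @return An object of class `weight_space`.
#' @export
weight_space <- function(ranking, delta = 1e-6, band = 1e-6) {
  ranking <- as.character(ranking)
  if (length(ranking) < 2) rlang::abort("need at least two criteria")
  if (anyDuplicated(ranking)) {
    rlang::abort("ranking must be a strict total order (duplicate ids found)")
  }
  if (anyNA(ranking)) rlang::abort("ranking ids must not be missing")
  stopifnot(delta >= 0, band >= 0)
  n <- length(ranking)
  A <- matrix(0, n - 1, n, dimnames = list(NULL, ranking))
  for (r in seq_len(n - 1)) {
    A[r, r] <- -1
    A[r, r + 1] <- 1
  }
  structure(
    list(
      criteria = ranking,
      ranking = ranking,
      delta = delta,
      band = band,
      A = A,
      dir = rep("<=", n - 1),
      rhs = rep(-delta, n - 1),
      labels = paste0("rank: k[", ranking[-n], "] >= k[", ranking[-1], "] + delta"),
      statements = list()
    ),
    class = "weight_space"
  )
}

#' @export
print.weight_space <- function(x, ...) {
  cat("<weight_space> ", length(x$criteria), " criteria, ranking: ",
      paste(x$ranking, collapse = " > "), "\n", sep = "")
  cat("  ", nrow(x$A), " linear constraints (", length(x$statements),
      " from tradeoff statements), delta = ", x$delta, "\n", sep = "")
  invisible(x)
}

#' A tradeoff statement
#'
#' Records the decision maker's answer to one tradeoff question comparing a
#' hypothetical consequence at normalized value `level` on the higher-ranked
#' criterion (worst on all others) with the best consequence on the
#' lower-ranked criterion (worst on all others).
#'
#' * answer `"A"` (hypothetical preferred): adds \eqn{k_j \le k_i\,v - \delta},
#' * answer `"B"` (best-on-lower preferred): adds \eqn{k_j \ge k_i\,v + \delta},
#' * answer `"indifferent"`: adds the two-sided band
#'   \eqn{|k_j - k_i\,v| \le} `band`.
#'
#' @param higher,lower Criterion ids, `higher` ranked above `lower`.
#' @param level Normalized value of the hypothetical consequence, in (0, 1).
#' @param answer One of `"A"`, `"B"`, `"indifferent"`.
#' @return An object of class `tradeoff_statement`.
#' @export
tradeoff_statement <- function(higher, lower, level,
                               answer = c("A", "B", "indifferent")) {
  answer <- match.arg(answer)
  stopifnot(is.character(higher), is.character(lower),
            length(higher) == 1, length(lower) == 1)
  if (!(level > 0 && level < 1)) {
    rlang::abort("hypothetical level must have normalized value in (0, 1)")
  }
  structure(list(higher = higher, lower = lower, level = level,
                 answer = answer),
            class = "tradeoff_statement")
}

#' @export
print.tradeoff_statement <- function(x, ...) {
  cat("<tradeoff_statement> ", x$higher, " at level ", signif(x$level, 4),
      " vs best ", x$lower, ": answer ", x$answer, "\n", sep = "")
  invisible(x)
}

#' Shrink a weight space with a tradeoff statement
#'
#' Returns a new space with the statement's linear constraint(s) appended;
#' the input space is unchanged.  If the constraint makes the space empty an
#' error of class `fitradeoff_inconsistent` is raised, carrying the
#' offending statement.
#'
#' @param space A [weight_space()].
#' @param statement A [tradeoff_statement()].
#' @param band Override of the space's indifference band.
#' @return The shrunken `weight_space`.
#' @export
add_statement <- function(space, statement, band = NULL) {
  stopifnot(inherits(space, "weight_space"),
            inherits(statement, "tradeoff_statement"))
  band <- band %||% space$band
  crits <- space$criteria
  for (id in c(statement$higher, statement$lower)) {
    if (!id %in% crits) rlang::abort(paste0("unknown criterion: ", id))
  }
  ri <- match(statement$higher, space$ranking)
  rj <- match(statement$lower, space$ranking)
  if (ri >= rj) {
    rlang::abort("statement must compare a higher-ranked criterion with a lower-ranked one")
  }
  n <- length(crits)
  e <- function(id) { v <- numeric(n); v[match(id, crits)] <- 1; v }
  row_ij <- e(statement$lower) - statement$level * e(statement$higher)
  lab <- paste0("stmt: k[", statement$lower, "] vs ", signif(statement$level, 6),
                " * k[", statement$higher, "] (", statement$answer, ")")
  new <- space
  if (statement$answer == "A") {
    new$A <- rbind(new$A, row_ij)
    new$dir <- c(new$dir, "<=")
    new$rhs <- c(new$rhs, -space$delta)
    new$labels <- c(new$labels, lab)
  } else if (statement$answer == "B") {
    new$A <- rbind(new$A, -row_ij)
    new$dir <- c(new$dir, "<=")
    new$rhs <- c(new$rhs, -space$delta)
    new$labels <- c(new$labels, lab)
  } else {
    new$A <- rbind(new$A, row_ij, -row_ij)
    new$dir <- c(new$dir, "<=", "<=")
    new$rhs <- c(new$rhs, band, band)
    new$labels <- c(new$labels, lab, lab)
  }
  rownames(new$A) <- NULL
  new$statements <- c(new$statements, list(statement))
  if (!is_feasible(new)) {
    rlang::abort(
      paste0("tradeoff statement makes the weight space infeasible: ", lab),
      class = "fitradeoff_inconsistent",
      statement = statement
    )
  }
  new
}

#' Is a weight space non-empty?
#'
#' @param space A [weight_space()].
#' @return `TRUE` if some scale-constant vector satisfies all constraints.
#' @export
is_feasible <- function(space) {
  stopifnot(inherits(space, "weight_space"))
  res <- space_lp(space, rep(0, length(space$criteria)))
  res$status != "infeasible"
}

#' @keywords internal
#' @noRd
stop_if_infeasible <- function(space) {
  if (!is_feasible(space)) {
    rlang::abort("weight space is infeasible", class = "fitradeoff_inconsistent")
  }
}

#' Maximum additive value of alternatives over a weight space
#'
#' For each alternative, solves the linear program maximizing its additive
#' value over all scale-constant vectors in the space, and reports the
#' attaining weights.
#'
#' @param space A feasible [weight_space()].
#' @param problem A [decision_problem()] on the same criteria.
#' @param alternatives Optional subset of alternative ids.
#' @return A tibble with columns `alternative`, `max_value`, and `weights`
#'   (list-column of named argmax weight vectors).
#' @export
max_additive_value <- function(space, problem, alternatives = NULL) {
  stopifnot(inherits(space, "weight_space"), inherits(problem, "decision_problem"))
  check_same_criteria(space, problem)
  stop_if_infeasible(space)
  m <- normalized_matrix(problem)[, space$criteria, drop = FALSE]
  alts <- alternatives %||% problem$alternatives
  res <- purrr::map(alts, function(a) {
    sol <- space_lp(space, m[a, ])
    if (sol$status != "optimal") {
      rlang::abort(paste0("LP did not solve for alternative ", a,
                          " (status ", sol$status, ")"))
    }
    list(value = sol$value, k = stats::setNames(sol$x, space$criteria))
  })
  tibble::tibble(
    alternative = alts,
    max_value = purrr::map_dbl(res, "value"),
    weights = purrr::map(res, "k")
  )
}

#' Per-criterion weight bounds of a space
#'
#' Solves, for every criterion, the two linear programs minimizing and
#' maximizing its scale constant over the space; the resulting intervals are
#' the "minimum limit" / "maximum limit" rows shown to the decision maker.
#'
#' @param space A feasible [weight_space()].
#' @return A tibble of class `weight_bounds` with columns `criterion`,
#'   `lower`, `upper`, in ranking order.
#' @export
weight_bounds <- function(space) {
  stopifnot(inherits(space, "weight_space"))
  stop_if_infeasible(space)
  n <- length(space$criteria)
  res <- purrr::map(seq_len(n), function(i) {
    obj <- numeric(n)
    obj[i] <- 1
    lo <- space_lp(space, obj, maximize = FALSE)
    hi <- space_lp(space, obj, maximize = TRUE)
    c(lo = lo$value, hi = hi$value)
  })
  out <- tibble::tibble(
    criterion = space$criteria,
    lower = pmax(0, purrr::map_dbl(res, "lo")),
    upper = pmin(1, purrr::map_dbl(res, "hi"))
  )
  class(out) <- c("weight_bounds", class(out))
  attr(out, "ranking") <- space$ranking
  out
}

#' Feasible interval of the weight ratio of a ranked pair
#'
#' Bounds of \eqn{k_j / k_i} (lower-ranked over higher-ranked) over the
#' space, computed exactly by a Charnes-Cooper transformed linear program.
#'
#' @param space A feasible [weight_space()].
#' @param higher,lower Criterion ids with `higher` ranked above `lower`.
#' @return Named numeric `c(lower =, upper =)`, a subinterval of `[0, 1]`.
#' @export
ratio_bounds <- function(space, higher, lower) {
  stopifnot(inherits(space, "weight_space"))
  crits <- space$criteria
  i <- match(higher, crits)
  j <- match(lower, crits)
  if (is.na(i) || is.na(j)) rlang::abort("unknown criterion in ratio_bounds")
  if (match(higher, space$ranking) >= match(lower, space$ranking)) {
    rlang::abort("`higher` must be ranked above `lower`")
  }
  n <- length(crits)
  # Charnes-Cooper: variables y_1..y_n (= k * t), t; each space row
  # a'k (dir) rhs becomes a'y - rhs * t (dir) 0; plus sum(y) = t, y_i = 1,
  # and a cap on t to keep the LP bounded.
  A <- rbind(
    cbind(space$A, -space$rhs),
    c(rep(0, n), 1),
    c(rep(1, n), -1),
    c(as.numeric(seq_len(n) == i), 0)
  )
  dir <- c(space$dir, "<=", "==", "==")
  rhs <- c(rep(0, nrow(space$A)), 1e7, 0, 1)
  obj <- c(as.numeric(seq_len(n) == j), 0)
  lo <- lp_solve(obj, A, dir, rhs, maximize = FALSE)
  hi <- lp_solve(obj, A, dir, rhs, maximize = TRUE)
  if (lo$status == "infeasible" || hi$status == "infeasible") {
    rlang::abort("weight space is infeasible", class = "fitradeoff_inconsistent")
  }
  c(lower = max(0, lo$value), upper = min(1, hi$value))
}

#' @keywords internal
#' @noRd
check_same_criteria <- function(space, problem) {
  if (!setequal(space$criteria, problem$criteria)) {
    rlang::abort("space and problem are defined on different criteria")
  }
  invisible(TRUE)
}

#' @export
tidy.weight_space <- function(x, ...) {
  tibble::tibble(
    label = x$labels,
    dplyr::as_tibble(x$A),
    dir = x$dir,
    rhs = x$rhs
  )
}

#' @export
glance.weight_space <- function(x, ...) {
  tibble::tibble(
    n_criteria = length(x$criteria),
    n_constraints = nrow(x$A),
    n_statements = length(x$statements),
    delta = x$delta,
    feasible = is_feasible(x)
  )
}
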