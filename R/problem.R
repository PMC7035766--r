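#' Build a decision problem from a long consequence table
#'
#' A decision problem bundles the alternatives, the criteria, the raw
#' consequence matrix and the per-criterion value functions of an additive
#' multi-attribute value model.  Consequences are raw scores on each criterion
#' (for example summed questionnaire points); the value functions fitted here
#' are affine min-max maps over the observed column range, so the best raw
#' score on a criterion is worth 1 and the worst 0.  All criteria are treated
#' as benefit criteria (higher raw score is better).
#'
#' @param data A data frame in long format with one row per
#'   (alternative, criterion) cell.
#' @param alternative,criterion,score Column names (tidy-select style) holding
#'   the alternative id, the criterion id and the raw score.
#' @return An object of class `decision_problem`.
#' @examples
#' consequences <- tibble::tribble(
#'   ~alternative, ~criterion, ~score,
#'   "a1", "c1", 10, "a1", "c2", 0,
#'   "a2", "c1", 5,  "a2", "c2", 8
#' )
#' decision_problem(consequences)
#' @export
decision_problem <- function(data, alternative = "alternative",
                             criterion = "criterion", score = "score") {
  stopifnot(is.data.frame(data))
  df <- tibble::tibble(
    alternative = as.character(data[[alternative]]),
    criterion = as.character(data[[criterion]]),
    score = as.numeric(data[[score]])
  )
  if (anyNA(df$alternative) || anyNA(df$criterion)) {
    rlang::abort("alternative and criterion ids must not be missing")
  }
  if (!all(is.finite(df$score))) {
    rlang::abort("consequence scores must be finite")
  }
  alts <- unique(df$alternative)
  crits <- unique(df$criterion)
  if (any(duplicated(df[c("alternative", "criterion")]))) {
    rlang::abort("duplicated (alternative, criterion) cells in consequence table")
  }
  if (nrow(df) != length(alts) * length(crits)) {
    rlang::abort("consequence table is not complete over alternatives x criteria")
  }
  m <- matrix(NA_real_, length(alts), length(crits),
              dimnames = list(alts, crits))
  m[cbind(df$alternative, df$criterion)] <- df$score
  new_decision_problem(m)
}

#' Coerce a consequence matrix to a decision problem
#'
#' @param x A numeric matrix with alternatives as rows and criteria as
#'   columns, both named.
#' @param ... Unused.
#' @return A `decision_problem`.
#' @export
as_decision_problem <- function(x, ...) {
  stopifnot(is.matrix(x), is.numeric(x))
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    rlang::abort("consequence matrix needs row (alternative) and column (criterion) names")
  }
  if (!all(is.finite(x))) rlang::abort("consequence scores must be finite")
  new_decision_problem(x)
}

new_decision_problem <- function(m) {
  if (anyDuplicated(rownames(m))) rlang::abort("alternative ids must be unique")
  if (anyDuplicated(colnames(m))) rlang::abort("criterion ids must be unique")
  vf <- tibble::tibble(
    criterion = colnames(m),
    minimum = apply(m, 2, min),
    maximum = apply(m, 2, max)
  )
  vf$degenerate <- vf$maximum == vf$minimum
  structure(
    list(
      alternatives = rownames(m),
      criteria = colnames(m),
      consequences = m,
      value_functions = vf
    ),
    class = "decision_problem"
  )
}

#' @export
print.decision_problem <- function(x, ...) {
  cat("<decision_problem> ", length(x$alternatives), " alternatives x ",
      length(x$criteria), " criteria\n", sep = "")
  print(x$consequences)
  if (any(x$value_functions$degenerate)) {
    cat("degenerate criteria:",
        paste(x$value_functions$criterion[x$value_functions$degenerate],
              collapse = ", "), "\n")
  }
  invisible(x)
}

#' Affine min-max value of a raw score
#'
#' Maps a raw consequence onto the 0-1 value scale of one criterion:
#' `(raw - minimum) / (maximum - minimum)`.
#'
#' @param raw Numeric raw score(s).
#' @param minimum,maximum Observed column extremes for the criterion.
#' @param criterion Optional criterion id, used in error messages.
#' @return Numeric value(s) in `[0, 1]` when `raw` lies in the observed range.
#' @export
minmax_value <- function(raw, minimum, maximum, criterion = NULL) {
  if (maximum <= minimum) {
    lab <- if (is.null(criterion)) "criterion" else paste0("criterion '", criterion, "'")
    rlang::abort(
      paste0("degenerate ", lab, ": maximum (", maximum,
             ") must exceed minimum (", minimum, ")"),
      class = "fitradeoff_degenerate"
    )
  }
  (raw - minimum) / (maximum - minimum)
}

# raw consequence matrix -> normalized matrix, stopping on degenerate columns
#' @keywords internal
#' @noRd
normalized_matrix <- function(problem) {
  vf <- problem$value_functions
  if (any(vf$degenerate)) {
    rlang::abort(
      paste0("degenerate criterion (constant column): ",
             paste(vf$criterion[vf$degenerate], collapse = ", ")),
      class = "fitradeoff_degenerate"
    )
  }
  sweep(sweep(problem$consequences, 2, vf$minimum, "-"),
        2, vf$maximum - vf$minimum, "/")
}

#' Normalize the consequences of a decision problem
#'
#' Applies the per-criterion affine min-max value functions; every column of
#' the result attains both 0 (at the worst observed raw score) and 1 (at the
#' best).
#'
#' @param problem A [decision_problem()].
#' @return A tibble with columns `alternative`, `criterion`, `value`.
#' @export
normalize_consequences <- function(problem) {
  stopifnot(inherits(problem, "decision_problem"))
  m <- normalized_matrix(problem)
  tibble::as_tibble(as.data.frame.table(m, stringsAsFactors = FALSE)) |>
    stats::setNames(c("alternative", "criterion", "value")) |>
    tibble::as_tibble()
}

#' @keywords internal
#' @noRd
check_weights <- function(weights, criteria, tol = 1e-9) {
  if (is.null(names(weights))) {
    if (length(weights) != length(criteria)) {
      rlang::abort("weight vector length does not match the number of criteria")
    }
    names(weights) <- criteria
  }
  missing <- setdiff(criteria, names(weights))
  if (length(missing) > 0) {
    rlang::abort(paste0("weights missing for criteria: ",
                        paste(missing, collapse = ", ")))
  }
  w <- weights[criteria]
  if (any(w < 0)) rlang::abort("scale constants must be non-negative")
  if (abs(sum(w) - 1) > tol) {
    rlang::abort(paste0("scale constants must sum to 1 (got ", sum(w), ")"))
  }
  w
}

#' Additive global value of alternatives
#'
#' Computes the additive multi-attribute value
#' \eqn{v(a) = \sum_i k_i \, v_i(x_{ai})} of each alternative at a given
#' vector of scale constants, using the problem's min-max normalized
#' consequences.
#'
#' @param problem A [decision_problem()].
#' @param weights Numeric vector of scale constants, named by criterion id
#'   (or unnamed in the problem's criteria order); must be non-negative and
#'   sum to 1 within `tol`.
#' @param alternatives Optional character vector restricting the output.
#' @param tol Tolerance on the weight sum.
#' @return A tibble with columns `alternative` and `value`, in `[0, 1]`.
#' @export
additive_value <- function(problem, weights, alternatives = NULL, tol = 1e-9) {
  stopifnot(inherits(problem, "decision_problem"))
  w <- check_weights(weights, problem$criteria, tol)
  m <- normalized_matrix(problem)
  if (!is.null(alternatives)) {
    unknown <- setdiff(alternatives, problem$alternatives)
    if (length(unknown) > 0) {
      rlang::abort(paste0("unknown alternatives: ", paste(unknown, collapse = ", ")))
    }
    m <- m[alternatives, , drop = FALSE]
  }
  tibble::tibble(
    alternative = rownames(m),
    value = as.numeric(m %*% w)
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
tidy.decision_problem <- function(x, normalized = FALSE, ...) {
  if (normalized) return(normalize_consequences(x))
  tibble::as_tibble(as.data.frame.table(x$consequences, stringsAsFactors = FALSE)) |>
    stats::setNames(c("alternative", "criterion", "score")) |>
    tibble::as_tibble()
}

#' @export
glance.decision_problem <- function(x, ...) {
  tibble::tibble(
    n_alternatives = length(x$alternatives),
    n_criteria = length(x$criteria),
    n_degenerate = sum(x$value_functions$degenerate)
  )
}
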