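#' Criteria tree
#'
#' A two-level tree of criteria and subcriteria, as used when a decision
#' panel decomposes each evaluation criterion into finer questionnaire items.
#'
#' @param data A data frame with one row per subcriterion.
#' @param criterion,subcriterion Column names holding the parent criterion id
#'   and the subcriterion id.
#' @return A tibble of class `criteria_tree` with columns `criterion` and
#'   `subcriterion`.
#' @export
criteria_tree <- function(data, criterion = "criterion",
                          subcriterion = "subcriterion") {
  stopifnot(is.data.frame(data))
  tree <- tibble::tibble(
    criterion = as.character(data[[criterion]]),
    subcriterion = as.character(data[[subcriterion]])
  )
  if (anyNA(tree)) rlang::abort("criteria tree ids must not be missing")
  if (anyDuplicated(tree$subcriterion)) {
    dup <- unique(tree$subcriterion[duplicated(tree$subcriterion)])
    rlang::abort(paste0("subcriterion ids must be unique (each subcriterion has ",
                        "exactly one parent): ", paste(dup, collapse = ", ")))
  }
  class(tree) <- c("criteria_tree", class(tree))
  tree
}

#' @export
print.criteria_tree <- function(x, ...) {
  cat("<criteria_tree> ", dplyr::n_distinct(x$criterion), " criteria, ",
      nrow(x), " subcriteria\n", sep = "")
  NextMethod()
}

#' Prune a criteria tree to the subcriteria approved by the decision group
#'
#' Subcriteria not approved during validation are dropped; criteria left with
#' no subcriteria are removed entirely.
#'
#' @param tree A [criteria_tree()].
#' @param approved Character vector of approved subcriterion ids.
#' @return The pruned `criteria_tree`.
#' @export
validate_tree <- function(tree, approved) {
  stopifnot(inherits(tree, "criteria_tree"))
  unknown <- setdiff(approved, tree$subcriterion)
  if (length(unknown) > 0) {
    rlang::abort(paste0("approved ids not in the tree: ",
                        paste(unknown, collapse = ", ")))
  }
  out <- dplyr::filter(tree, .data$subcriterion %in% approved)
  class(out) <- class(tree)
  out
}

#' @export
glance.criteria_tree <- function(x, ...) {
  tibble::tibble(
    n_criteria = dplyr::n_distinct(x$criterion),
    n_subcriteria = nrow(x)
  )
}

#' Aggregate Likert questionnaire responses by the mean
#'
#' Averages per-respondent Likert scores into one mean per subcriterion, the
#' standard aggregation when a group of respondents cannot converge on a
#' joint judgement.
#'
#' @param responses A data frame with columns `respondent`, `subcriterion`
#'   and `score` (and optionally `criterion`, carried through).
#' @param scale Allowed score range, default the five-point scale `c(1, 5)`.
#' @return A tibble with one row per subcriterion and column `mean_score`
#'   (unrounded; round only for display).
#' @export
aggregate_likert_mean <- function(responses, scale = c(1, 5)) {
  stopifnot(is.data.frame(responses))
  if (nrow(responses) == 0) rlang::abort("empty response set")
  needed <- c("respondent", "subcriterion", "score")
  missing <- setdiff(needed, names(responses))
  if (length(missing) > 0) {
    rlang::abort(paste0("responses lack columns: ", paste(missing, collapse = ", ")))
  }
  if (any(responses$score < scale[1] | responses$score > scale[2])) {
    rlang::abort(paste0("scores outside the Likert scale [", scale[1], ", ",
                        scale[2], "]"))
  }
  keys <- intersect(c("criterion", "subcriterion"), names(responses))
  responses |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(
      n_respondents = dplyr::n(),
      mean_score = mean(.data$score),
      .groups = "drop"
    )
}

#' Aggregate specialist subcriterion scores into a consequence table
#'
#' Sums an alternative's scores over the subcriteria of each criterion,
#' producing the criterion-level decision matrix.  An optional per-
#' subcriterion weight vector turns the sum into a weighted sum; by default
#' all subcriteria count equally (weight 1).
#'
#' @param scores A data frame with columns `alternative`, `subcriterion`,
#'   `score`; scores on the 0-5 specialist scale.
#' @param tree A [criteria_tree()]; scoring must be complete over its leaves.
#' @param subweights Optional named numeric vector of subcriterion weights
#'   (default: unweighted sum).
#' @param scale Allowed score range, default `c(0, 5)`.
#' @return A tibble with columns `alternative`, `criterion`, `score`, ready
#'   for [decision_problem()].
#' @export
aggregate_specialist_sum <- function(scores, tree, subweights = NULL,
                                     scale = c(0, 5)) {
  stopifnot(is.data.frame(scores), inherits(tree, "criteria_tree"))
  needed <- c("alternative", "subcriterion", "score")
  missing <- setdiff(needed, names(scores))
  if (length(missing) > 0) {
    rlang::abort(paste0("scores lack columns: ", paste(missing, collapse = ", ")))
  }
  if (any(scores$score < scale[1] | scores$score > scale[2])) {
    rlang::abort(paste0("scores outside [", scale[1], ", ", scale[2], "]"))
  }
  alts <- unique(scores$alternative)
  have <- dplyr::distinct(scores, .data$alternative, .data$subcriterion)
  want <- tidyr::expand_grid(alternative = alts,
                             subcriterion = tree$subcriterion)
  gap <- dplyr::anti_join(want, have, by = c("alternative", "subcriterion"))
  if (nrow(gap) > 0) {
    rlang::abort(paste0(
      "missing (alternative, subcriterion) cells, e.g. ",
      gap$alternative[1], " / ", gap$subcriterion[1],
      " (", nrow(gap), " missing in total)"
    ))
  }
  w <- if (is.null(subweights)) {
    stats::setNames(rep(1, nrow(tree)), tree$subcriterion)
  } else {
    if (is.null(names(subweights)) ||
        !all(tree$subcriterion %in% names(subweights))) {
      rlang::abort("subweights must be named and cover every subcriterion")
    }
    subweights
  }
  scores |>
    dplyr::select(dplyr::all_of(needed)) |>
    dplyr::semi_join(tree, by = "subcriterion") |>
    dplyr::inner_join(tree, by = "subcriterion") |>
    dplyr::mutate(w = unname(w[.data$subcriterion])) |>
    dplyr::group_by(.data$alternative, .data$criterion) |>
    dplyr::summarise(score = sum(.data$score * .data$w), .groups = "drop")
}
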