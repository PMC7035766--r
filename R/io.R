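# Readers and writers.  All tables are plain CSV (UTF-8) with a configurable
# decimal separator, since questionnaire exports in many locales print
# decimal commas; JSON carries structured objects.

#' @keywords internal
#' @noRd
csv_locale <- function(dec = ".") {
  stopifnot(dec %in% c(".", ","))
  readr::locale(decimal_mark = dec,
                grouping_mark = if (dec == ",") "." else ",")
}

#' Read a long-format score table
#'
#' Reads CSV files holding questionnaire scores in long format, e.g.
#' `alternative,subcriterion,score` for specialist matrices or
#' `respondent,subcriterion,score` for Likert responses.  The delimiter is
#' `;` when the decimal separator is `,`, and `,` otherwise.
#'
#' @param path File path.
#' @param dec Decimal separator, `"."` or `","`.
#' @return A tibble.
#' @export
read_scores_csv <- function(path, dec = ".") {
  if (!file.exists(path)) rlang::abort(paste0("no such file: ", path))
  delim <- if (dec == ",") ";" else ","
  out <- readr::read_delim(path, delim = delim, locale = csv_locale(dec),
                           show_col_types = FALSE, trim_ws = TRUE)
  if (nrow(out) == 0) rlang::abort(paste0("empty score file: ", path))
  out
}

#' Write a long-format score table
#'
#' @param data A data frame.
#' @param path File path.
#' @param dec Decimal separator, `"."` or `","`.
#' @export
write_scores_csv <- function(data, path, dec = ".") {
  delim <- if (dec == ",") ";" else ","
  x <- data
  if (dec == ",") {
    num <- vapply(x, is.numeric, logical(1))
    x[num] <- lapply(x[num], function(v) sub(".", ",", format(v, trim = TRUE,
                                                              scientific = FALSE),
                                             fixed = TRUE))
  }
  readr::write_delim(x, path, delim = delim)
  invisible(path)
}

#' Serialize a decision problem to JSON
#'
#' @param problem A [decision_problem()].
#' @param path Optional file path; if `NULL` the JSON string is returned.
#' @export
problem_to_json <- function(problem, path = NULL) {
  stopifnot(inherits(problem, "decision_problem"))
  obj <- list(
    alternatives = problem$alternatives,
    criteria = problem$criteria,
    consequences = lapply(seq_len(nrow(problem$consequences)),
                          function(i) unname(problem$consequences[i, ]))
  )
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}

#' Deserialize a decision problem from JSON
#'
#' @param x A JSON string or file path produced by [problem_to_json()].
#' @return A [decision_problem()].
#' @export
problem_from_json <- function(x) {
  obj <- jsonlite::fromJSON(x)
  rows <- obj$consequences
  if (is.list(rows)) rows <- do.call(rbind, rows)
  m <- matrix(as.numeric(rows), nrow = length(obj$alternatives),
              dimnames = list(obj$alternatives, obj$criteria))
  new_decision_problem(m)
}

#' Serialize a weight space to JSON
#'
#' Records the ranking, the strictness and band parameters, and every
#' tradeoff statement, enough to rebuild the space exactly.
#'
#' @param space A [weight_space()].
#' @param path Optional file path; if `NULL` the JSON string is returned.
#' @export
space_to_json <- function(space, path = NULL) {
  stopifnot(inherits(space, "weight_space"))
  obj <- list(
    ranking = space$ranking,
    delta = space$delta,
    band = space$band,
    statements = purrr::map(space$statements, function(s) {
      list(higher = s$higher, lower = s$lower, level = s$level,
           answer = s$answer)
    })
  )
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}

#' Deserialize a weight space from JSON
#'
#' @param x A JSON string or file path produced by [space_to_json()].
#' @return A [weight_space()].
#' @export
space_from_json <- function(x) {
  obj <- jsonlite::fromJSON(x, simplifyDataFrame = FALSE)
  space <- weight_space(obj$ranking, delta = obj$delta, band = obj$band)
  for (s in obj$statements) {
    space <- add_statement(
      space, tradeoff_statement(s$higher, s$lower, s$level, s$answer))
  }
  space
}

#' Export weight bounds as CSV
#'
#' @param bounds A [weight_bounds()] tibble.
#' @param path File path.
#' @param dec Decimal separator.
#' @export
write_weight_bounds_csv <- function(bounds, path, dec = ".") {
  write_scores_csv(bounds, path, dec = dec)
}

#' Export a survivor table as CSV
#'
#' One row per potentially optimal alternative, with its LP maximum value
#' and the attaining weight of each criterion in ranking order — the layout
#' of the "possible solutions" table shown to the decision makers.
#'
#' @param set A `potential_optimal_set`.
#' @param path File path.
#' @param dec Decimal separator.
#' @export
write_survivor_csv <- function(set, path, dec = ".") {
  stopifnot(inherits(set, "potential_optimal_set"))
  space <- attr(set, "space")
  surv <- set[set$potentially_optimal, ]
  wide <- purrr::map(surv$weights, ~ tibble::as_tibble(as.list(.x))) |>
    dplyr::bind_rows()
  names(wide) <- paste0("k_", names(wide))
  out <- dplyr::bind_cols(
    tibble::tibble(alternative = surv$alternative),
    wide,
    tibble::tibble(max_value = surv$max_value)
  )
  write_scores_csv(out, path, dec = dec)
}

#' Export a session log as line-delimited JSON
#'
#' One JSON record per elicitation step, including the question, the
#' answer, the surviving alternatives and the weight bounds after the step.
#'
#' @param session A `fitradeoff_session`.
#' @param path File path.
#' @export
write_session_log <- function(session, path) {
  stopifnot(inherits(session, "fitradeoff_session"))
  lines <- purrr::map_chr(seq_len(nrow(session$log)), function(i) {
    row <- session$log[i, ]
    jsonlite::toJSON(list(
      question_no = row$question_no,
      higher = row$higher,
      lower = row$lower,
      level = row$level,
      answer = row$answer,
      n_survivors = row$n_survivors,
      survivors = row$survivors[[1]],
      bounds = as.data.frame(row$bounds[[1]])
    ), auto_unbox = TRUE, digits = NA, na = "null")
  })
  writeLines(lines, path)
  invisible(path)
}

#' Read a session log written by [write_session_log()]
#'
#' @param path File path.
#' @return A tibble with one row per step.
#' @export
read_session_log <- function(path) {
  lines <- readLines(path)
  purrr::map(lines, function(l) {
    rec <- jsonlite::fromJSON(l)
    tibble::tibble(
      question_no = rec$question_no,
      higher = rec$higher %||% NA_character_,
      lower = rec$lower %||% NA_character_,
      level = rec$level %||% NA_real_,
      answer = rec$answer %||% NA_character_,
      n_survivors = rec$n_survivors,
      survivors = list(rec$survivors),
      bounds = list(tibble::as_tibble(rec$bounds))
    )
  }) |> dplyr::bind_rows()
}
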