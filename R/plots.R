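# ggplot2 displays of the objects a decision maker is shown during a
# session: weight-bound intervals, per-criterion comparison bars for the
# surviving alternatives, and the trajectory of a session.

#' @export
autoplot.weight_bounds <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$criterion <- factor(df$criterion, levels = attr(object, "ranking"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$criterion)) +
    ggplot2::geom_linerange(ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
                            linewidth = 2, colour = "steelblue") +
    ggplot2::geom_point(ggplot2::aes(y = .data$lower), size = 2) +
    ggplot2::geom_point(ggplot2::aes(y = .data$upper), size = 2) +
    ggplot2::labs(x = NULL, y = "scale constant",
                  title = "Feasible weight bounds") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' @export
plot.weight_bounds <- function(x, ...) print(autoplot(x, ...))

#' @export
autoplot.potential_optimal_set <- function(object, normalized = TRUE, ...) {
  problem <- attr(object, "problem")
  space <- attr(object, "space")
  keep <- survivors(object)
  df <- if (normalized) normalize_consequences(problem) else
    dplyr::rename(tidy(problem), value = "score")
  df <- dplyr::filter(df, .data$alternative %in% keep)
  df$criterion <- factor(df$criterion, levels = space$ranking)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$criterion, y = .data$value,
                                   fill = .data$alternative)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL,
                  y = if (normalized) "normalized value" else "raw score",
                  title = "Potentially optimal alternatives by criterion") +
    ggplot2::theme_minimal()
}

#' @export
plot.potential_optimal_set <- function(x, ...) print(autoplot(x, ...))

#' @export
autoplot.fitradeoff_session <- function(object, ...) {
  log <- object$log
  bounds <- purrr::map2(log$bounds, log$question_no,
                        ~ dplyr::mutate(tibble::as_tibble(.x), question_no = .y)) |>
    dplyr::bind_rows()
  bounds$criterion <- factor(bounds$criterion, levels = object$ranking)
  ggplot2::ggplot(bounds, ggplot2::aes(x = .data$question_no)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
                         fill = "steelblue", alpha = 0.4) +
    ggplot2::facet_wrap(ggplot2::vars(.data$criterion)) +
    ggplot2::labs(x = "question", y = "scale constant",
                  title = "Weight bounds along the session",
                  subtitle = paste0("recommendation: ", object$recommendation)) +
    ggplot2::theme_minimal()
}

#' @export
plot.fitradeoff_session <- function(x, ...) print(autoplot(x, ...))
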