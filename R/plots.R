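#' Posterior densities of a group-level parameter mean
#'
#' @param object An `igt_hba`.
#' @param param Parameter to display (default `"lambda"`).
#' @param ... Unused.
#' @return A ggplot: one density per group of the natural-scale group
#'   mean draws, with group means marked.
#' @export
autoplot.igt_hba <- function(object, param = "lambda", ...) {
  draws <- purrr::imap_dfr(object$groups, function(gf, g) {
    tibble::tibble(group = g, value = group_mean_draws(object, param, g))
  })
  means <- draws |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(m = mean(.data$value), .groups = "drop")
  ggplot2::ggplot(draws, ggplot2::aes(x = .data$value, fill = .data$group)) +
    ggplot2::geom_density(alpha = 0.4, colour = NA) +
    ggplot2::geom_vline(data = means,
                        ggplot2::aes(xintercept = .data$m,
                                     colour = .data$group),
                        linetype = "dashed", show.legend = FALSE) +
    ggplot2::labs(x = paste0("group-level mean of ", param),
                  y = "posterior density", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Mean net score per block by group
#'
#' @param x Cohort or labeled trials tibble.
#' @param block_size Trials per block, default 20.
#' @return A ggplot.
#' @export
plot_net_scores <- function(x, block_size = 20) {
  ns <- net_scores(cohort_trials(x), block_size) |>
    dplyr::group_by(.data$group, .data$block) |>
    dplyr::summarise(mean = mean(.data$net_score), .groups = "drop")
  ggplot2::ggplot(ns, ggplot2::aes(x = .data$block, y = .data$mean,
                                   colour = .data$group)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey70") +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = paste0("block (", block_size, " trials)"),
                  y = "mean net score", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Deck-choice proportions
#'
#' @param x Cohort or trials tibble; grouped bars when a `group` column
#'   is present.
#' @return A ggplot.
#' @export
plot_deck_proportions <- function(x) {
  trials <- cohort_trials(x)
  if ("group" %in% names(trials) && !anyNA(trials$group)) {
    props <- trials |>
      dplyr::group_by(.data$group) |>
      dplyr::group_modify(~ deck_proportions(.x))
    ggplot2::ggplot(props, ggplot2::aes(x = .data$deck, y = .data$prop,
                                        fill = .data$group)) +
      ggplot2::geom_col(position = "dodge") +
      ggplot2::labs(x = "deck", y = "proportion of choices", fill = NULL) +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(deck_proportions(trials),
                    ggplot2::aes(x = .data$deck, y = .data$prop)) +
      ggplot2::geom_col(fill = "steelblue") +
      ggplot2::labs(x = "deck", y = "proportion of choices") +
      ggplot2::theme_minimal()
  }
}
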