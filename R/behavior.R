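# Behavioral IGT indices. These use ALL trials of a session: the
# depletion-truncation rule applies to model fitting only.

#' Per-block net scores
#'
#' The net score of a block is the number of advantageous picks (decks C,
#' D) minus disadvantageous picks (decks A, B); negative values indicate
#' impaired performance. Blocks of `block_size` trials (default 20, i.e.
#' five blocks over a 100-trial session); a final partial block, if any,
#' is reported as its own block.
#'
#' @param x Cohort or trials tibble (one or many subjects).
#' @param block_size Trials per block, default 20.
#' @return Tibble: `subject_id`, `group` (if present), `block`,
#'   `n_trials`, `net_score`.
#' @examples
#' s <- simulate_agent(pvl_params(0.3, 1.5, 0.6, 1), "pvl_decay", seed = 1)
#' net_scores(s)
#' @export
net_scores <- function(x, block_size = 20) {
  trials <- cohort_trials(x)
  if (nrow(trials) == 0) abort("empty session")
  stopifnot(block_size >= 1)
  grp <- intersect(c("subject_id", "group"), names(trials))
  trials |>
    dplyr::mutate(block = (.data$trial - 1) %/% block_size + 1) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(grp, "block")))) |>
    dplyr::summarise(
      n_trials = dplyr::n(),
      net_score = sum(.data$deck %in% c("C", "D")) -
        sum(.data$deck %in% c("A", "B")),
      .groups = "drop"
    )
}

#' Overall deck-choice proportions
#'
#' Counts over all included trials divided by the total; decks never
#' chosen appear with proportion 0.
#'
#' @param x Cohort or trials tibble.
#' @return Tibble: `deck`, `n`, `prop` (proportions sum to 1).
#' @export
deck_proportions <- function(x) {
  trials <- cohort_trials(x)
  if (nrow(trials) == 0) abort("empty input")
  deck_index(trials$deck)  # validates labels
  counts <- table(factor(trials$deck, levels = DECKS))
  tibble::tibble(deck = DECKS, n = as.integer(counts),
                 prop = as.numeric(counts) / nrow(trials))
}

#' Group-level behavioral summary
#'
#' @param x Cohort or labeled trials tibble.
#' @param block_size Trials per net-score block, default 20.
#' @return List of class `igt_behavior_summary` with tibbles
#'   `net_scores` (per group and block: mean, SD), `overall` (per group:
#'   mean and SD over subjects of the subject's mean per-block net score)
#'   and `deck_proportions` (per group mean subject-level proportions).
#' @export
group_behavior_summary <- function(x, block_size = 20) {
  trials <- cohort_trials(x)
  if (!"group" %in% names(trials) || anyNA(trials$group))
    abort("trials must carry a `group` label")
  if (any(dplyr::count(trials, .data$group)$n == 0))
    abort("every group must have at least one subject")
  ns <- net_scores(trials, block_size)
  per_block <- ns |>
    dplyr::group_by(.data$group, .data$block) |>
    dplyr::summarise(mean = mean(.data$net_score),
                     sd = if (dplyr::n() > 1) sd(.data$net_score) else 0,
                     .groups = "drop")
  overall <- ns |>
    dplyr::group_by(.data$group, .data$subject_id) |>
    dplyr::summarise(m = mean(.data$net_score), .groups = "drop_last") |>
    dplyr::summarise(mean = mean(.data$m),
                     sd = if (dplyr::n() > 1) sd(.data$m) else 0,
                     .groups = "drop")
  props <- trials |>
    dplyr::group_by(.data$group, .data$subject_id) |>
    dplyr::group_modify(~ deck_proportions(.x)) |>
    dplyr::group_by(.data$group, .data$deck) |>
    dplyr::summarise(prop = mean(.data$prop), .groups = "drop")
  structure(list(net_scores = per_block, overall = overall,
                 deck_proportions = props, block_size = block_size),
            class = "igt_behavior_summary")
}

#' @export
print.igt_behavior_summary <- function(x, ...) {
  cat("Behavioral summary (blocks of", x$block_size, "trials)\n\n")
  cat("Mean (SD) net score per subject:\n")
  print(x$overall)
  cat("\nMean deck-choice proportions:\n")
  print(tidyr::pivot_wider(x$deck_proportions, names_from = "deck",
                           values_from = "prop"))
  invisible(x)
}
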