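#' Modeling horizon under the deck-depletion rule
#'
#' A deck chosen 60 times is depleted; from the next trial on the task is
#' a three-deck choice, so trials after the depleting trial are excluded
#' from model fitting. Returns the index of the trial on which some deck
#' receives its 60th pick (that trial itself is retained), or the number
#' of trials if no deck depletes; 0 for an empty session.
#'
#' @param trials A single subject's trial tibble (columns `trial`, `deck`),
#'   or a character vector of deck labels in trial order.
#' @return Integer modeling horizon.
#' @export
truncate_at_depletion <- function(trials) {
  deck <- if (is.character(trials)) trials else {
    stopifnot(is.data.frame(trials))
    if ("subject_id" %in% names(trials) &&
        dplyr::n_distinct(trials$subject_id) > 1)
      abort("`trials` must contain a single subject; see modeling_horizons()")
    trials$deck[order(trials$trial)]
  }
  n <- length(deck)
  if (n == 0) return(0L)
  idx <- deck_index(deck)
  hit <- Inf
  for (j in 1:4) {
    k <- which(cumsum(idx == j) == 60L)
    if (length(k) > 0) hit <- min(hit, k[1])
  }
  if (is.finite(hit)) as.integer(hit) else n
}

#' Per-subject modeling horizons for a cohort
#'
#' @param x An `igt_cohort` or a long trials tibble.
#' @return Tibble with `subject_id`, `n_trials`, `horizon` and a logical
#'   `depleted` flag.
#' @export
modeling_horizons <- function(x) {
  trials <- cohort_trials(x)
  trials |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::arrange(.data$trial, .by_group = TRUE) |>
    dplyr::summarise(
      n_trials = dplyr::n(),
      horizon = truncate_at_depletion(.data$deck),
      .groups = "drop"
    ) |>
    dplyr::mutate(depleted = .data$horizon < .data$n_trials)
}

#' Simulate one agent playing the modified IGT
#'
#' Forward-simulates a session: on every trial the agent chooses among the
#' non-depleted decks with softmax probabilities over its current deck
#' expectancies, receives the deck's next card, and updates expectancies
#' under the chosen model's learning rule. Expectancies start at zero, so
#' the first choice is uniform.
#'
#' @param params Named parameter vector (see [pvl_params()], [evl_params()]).
#' @param model One of `"evl"`, `"pvl_delta"`, `"pvl_decay"`.
#' @param schedule Payoff schedule tibble; default [payoff_schedule()].
#' @param n_trials Number of trials, at most 240 (total cards). Default 100.
#' @param seed Optional integer; identical seeds give identical sessions.
#'   The caller's RNG state is preserved.
#' @param subject_id,group Labels attached to the output.
#' @return Trial tibble: `subject_id`, `group`, `trial`, `deck`, `win`,
#'   `loss`.
#' @examples
#' s <- simulate_agent(pvl_params(0.3, 1.5, 0.6, 1), "pvl_decay", seed = 1)
#' head(s)
#' @export
simulate_agent <- function(params, model = "pvl_decay",
                           schedule = payoff_schedule(), n_trials = 100,
                           seed = NULL, subject_id = "S01",
                           group = NA_character_) {
  info <- model_info(model)
  params <- validate_params(params, model)
  if (n_trials < 1 || n_trials > 240)
    abort("`n_trials` must be between 1 and 240 (the decks hold 240 cards)")
  validate_payoff_schedule(schedule)
  if (!is.null(seed)) withr::local_seed(seed)

  win_m <- loss_m <- matrix(0, nrow = 4, ncol = 60)
  for (j in 1:4) {
    d <- schedule[schedule$deck == DECKS[j], ]
    d <- d[order(d$card), ]
    win_m[j, ] <- d$win
    loss_m[j, ] <- d$loss
  }

  evl <- info$model == "evl"
  if (!evl) theta <- choice_sensitivity_pvl(params[["c"]])
  E <- numeric(4)
  drawn <- integer(4)
  deck <- integer(n_trials)
  win <- loss <- numeric(n_trials)
  for (t in seq_len(n_trials)) {
    avail <- which(drawn < 60L)
    if (evl) theta <- choice_sensitivity_evl(params[["c"]], t)
    p <- choice_probabilities(E, theta, DECKS[avail])
    j <- sample.int(4L, 1L, prob = p)
    drawn[j] <- drawn[j] + 1L
    deck[t] <- j
    win[t] <- win_m[j, drawn[j]]
    loss[t] <- loss_m[j, drawn[j]]
    if (evl) {
      u <- evl_valence(win[t], loss[t], params[["w"]])
      E <- delta_update(E, j, u, params[["phi"]])
    } else {
      u <- prospect_utility(win[t] + loss[t], params[["alpha"]], params[["lambda"]])
      E <- if (info$model == "pvl_decay") decay_update(E, j, u, params[["A"]])
           else delta_update(E, j, u, params[["A"]])
    }
  }
  tibble::tibble(
    subject_id = subject_id, group = group, trial = seq_len(n_trials),
    deck = DECKS[deck], win = win, loss = loss
  )
}
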