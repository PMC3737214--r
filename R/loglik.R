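#' Trial-level log-likelihood of a session
#'
#' Evaluates the exact log-likelihood of one subject's choice sequence
#' under a model: expectancies start at zero, each trial contributes
#' `log p(chosen deck | expectancies before the trial)` through the
#' softmax rule, and expectancies are then updated with the realized
#' outcome. Only trials up to the modeling horizon (deck-depletion rule)
#' enter the sum.
#'
#' @param trials A single subject's trial tibble with columns `trial`,
#'   `deck`, `win`, `loss`.
#' @param params Named parameter vector for `model`.
#' @param model One of `"evl"`, `"pvl_delta"`, `"pvl_decay"`.
#' @param horizon Number of trials to include; default
#'   [truncate_at_depletion()] of the session.
#' @return Log-likelihood (a single number, <= 0).
#' @examples
#' s <- simulate_agent(pvl_params(0.3, 1.5, 0.6, 1), "pvl_decay", seed = 1)
#' session_loglik(s, pvl_params(0.3, 1.5, 0.6, 1), "pvl_decay")
#' @export
session_loglik <- function(trials, params, model = "pvl_decay",
                           horizon = NULL) {
  info <- model_info(model)
  params <- validate_params(params, model, strict = FALSE)
  dat <- session_data(trials)
  horizon <- horizon %||% truncate_at_depletion(DECKS[dat$deck + 1L])
  if (horizon < 1) abort("session has no trials to model")
  session_loglik_cpp(dat$deck, dat$win, dat$loss, as.integer(horizon),
                     unname(params), info$code)
}

#' Per-trial one-step-ahead log predictive probabilities
#'
#' @inheritParams session_loglik
#' @return Numeric vector of length `horizon` whose sum is
#'   [session_loglik()].
#' @export
session_logp_trials <- function(trials, params, model = "pvl_decay",
                                horizon = NULL) {
  info <- model_info(model)
  params <- validate_params(params, model, strict = FALSE)
  dat <- session_data(trials)
  horizon <- horizon %||% truncate_at_depletion(DECKS[dat$deck + 1L])
  session_logp_trials_cpp(dat$deck, dat$win, dat$loss, as.integer(horizon),
                          unname(params), info$code)
}

# Convert one subject's trial tibble into 0-based deck indices plus
# win/loss vectors in trial order.
#' @keywords internal
session_data <- function(trials) {
  need <- c("trial", "deck", "win", "loss")
  miss <- setdiff(need, names(trials))
  if (length(miss) > 0)
    abort(paste0("trials are missing column(s): ", paste(miss, collapse = ", ")))
  if ("subject_id" %in% names(trials) &&
      dplyr::n_distinct(trials$subject_id) > 1)
    abort("`trials` must contain a single subject")
  trials <- trials[order(trials$trial), ]
  list(
    deck = deck_index(trials$deck) - 1L,
    win = as.double(trials$win),
    loss = as.double(trials$loss)
  )
}
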