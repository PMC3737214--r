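#' @keywords internal
DECKS <- c("A", "B", "C", "D")

# Model registry. Parameter order here is the order used everywhere:
# likelihood calls, latent vectors, MCMC draws, MLE output.
MODEL_INFO <- list(
  evl = list(
    model = "evl", code = 1L,
    params = c("w", "phi", "c"),
    lb = c(w = 0, phi = 0, c = -5),
    ub = c(w = 1, phi = 1, c = 5)
  ),
  pvl_delta = list(
    model = "pvl_delta", code = 2L,
    params = c("alpha", "lambda", "A", "c"),
    lb = c(alpha = 0, lambda = 0, A = 0, c = 0),
    ub = c(alpha = 1, lambda = 5, A = 1, c = 5)
  ),
  pvl_decay = list(
    model = "pvl_decay", code = 3L,
    params = c("alpha", "lambda", "A", "c"),
    lb = c(alpha = 0, lambda = 0, A = 0, c = 0),
    ub = c(alpha = 1, lambda = 5, A = 1, c = 5)
  )
)

#' Models implemented by igtrl
#'
#' @return Character vector of model identifiers: `"evl"` (Expectancy
#'   Valence Learning), `"pvl_delta"` (Prospect Valence Learning, delta
#'   rule), `"pvl_decay"` (Prospect Valence Learning, decay-reinforcement
#'   rule).
#' @export
igt_models <- function() names(MODEL_INFO)

#' @keywords internal
model_info <- function(model) {
  model <- match.arg(model, names(MODEL_INFO))
  MODEL_INFO[[model]]
}

#' @keywords internal
deck_index <- function(deck) {
  idx <- match(deck, DECKS)
  if (anyNA(idx)) {
    bad <- unique(deck[is.na(idx)])
    abort(paste0("unknown deck label(s): ", paste(bad, collapse = ", "),
                 " (expected A, B, C or D)"))
  }
  idx
}

#' Construct and validate PVL model parameters
#'
#' The Prospect Valence Learning models have four free parameters:
#' reward sensitivity `alpha` (utility curvature, 0 < alpha < 1), loss
#' aversion `lambda` (0 < lambda < 5), recency/learning `A` (0 < A < 1;
#' the decay factor under the decay-reinforcement rule, the learning rate
#' under the delta rule) and choice consistency `c` (0 < c < 5).
#'
#' @param alpha Utility shape (reward sensitivity), in (0, 1).
#' @param lambda Loss aversion, in (0, 5).
#' @param A Recency (decay factor or learning rate), in (0, 1).
#' @param c Choice consistency, in (0, 5).
#' @return Named numeric vector in canonical order.
#' @examples
#' pvl_params(alpha = 0.4, lambda = 1.5, A = 0.6, c = 1)
#' @export
pvl_params <- function(alpha, lambda, A, c) {
  validate_params(c(alpha = alpha, lambda = lambda, A = A, c = c), "pvl_decay")
}

#' Construct and validate EVL model parameters
#'
#' The Expectancy Valence Learning model has three free parameters:
#' attention to losses `w` (0 < w < 1), recency/learning rate `phi`
#' (0 < phi < 1) and consistency `c` (here bounded to (-5, 5); the EVL
#' choice sensitivity grows or shrinks with trial number as (t/10)^c).
#'
#' @param w Attention weight on losses, in (0, 1).
#' @param phi Recency / learning rate, in (0, 1).
#' @param c Consistency, in (-5, 5).
#' @return Named numeric vector in canonical order.
#' @export
evl_params <- function(w, phi, c) {
  validate_params(c(w = w, phi = phi, c = c), "evl")
}

#' @keywords internal
validate_params <- function(params, model, strict = TRUE) {
  info <- model_info(model)
  if (is.null(names(params)) || !setequal(names(params), info$params)) {
    abort(paste0("parameters for model '", info$model, "' must be named ",
                 paste(info$params, collapse = ", ")))
  }
  params <- params[info$params]
  if (any(!is.finite(params))) abort("parameters must be finite")
  out <- params <= info$lb | params >= info$ub
  if (strict && any(out)) {
    bad <- info$params[out]
    abort(paste0("parameter(s) out of bounds for model '", info$model, "': ",
                 paste(bad, collapse = ", ")))
  }
  params
}

#' Prospect utility of a net outcome
#'
#' The PVL outcome evaluation: `u = x^alpha` for gains and
#' `u = -lambda * |x|^alpha` for losses, applied to the net outcome
#' `x = win + loss` of a trial. Diminishing sensitivity comes from
#' `alpha < 1`; asymmetric treatment of losses from `lambda`.
#'
#' @param x Net outcome in dollars (vectorized).
#' @param alpha Utility shape, in (0, 1).
#' @param lambda Loss aversion, in (0, 5).
#' @return Utilities, same length as `x`.
#' @examples
#' prospect_utility(c(100, -100, 0), alpha = 0.5, lambda = 2)
#' @export
prospect_utility <- function(x, alpha, lambda) {
  ifelse(x >= 0, x^alpha, -lambda * abs(x)^alpha)
}

#' EVL valence of a win/loss pair
#'
#' The EVL outcome evaluation is linear: `u = (1 - w) * win - w * |loss|`,
#' where `w` is the attention weight on losses.
#'
#' @param win Win amount, >= 0 (vectorized).
#' @param loss Loss amount, <= 0 (vectorized).
#' @param w Attention to losses, in (0, 1).
#' @return Valences.
#' @export
evl_valence <- function(win, loss, w) {
  (1 - w) * win - w * abs(loss)
}

#' Decay-reinforcement expectancy update
#'
#' All four deck expectancies decay by the recency factor `A`; the chosen
#' deck then gains the current utility:
#' `E_j <- A * E_j + [j == chosen] * u`.
#'
#' @param E Numeric 4-vector of deck expectancies (order A, B, C, D).
#' @param chosen Deck label ("A".."D") or index (1..4).
#' @param u Utility of the realized outcome.
#' @param A Recency (decay) factor, in (0, 1); 0 and 1 are allowed for
#'   limiting analyses.
#' @return Updated 4-vector of expectancies.
#' @export
decay_update <- function(E, chosen, u, A) {
  stopifnot(length(E) == 4)
  j <- if (is.character(chosen)) deck_index(chosen) else as.integer(chosen)
  if (is.na(j) || j < 1L || j > 4L) abort("invalid deck")
  E <- A * E
  E[j] <- E[j] + u
  E
}

#' Delta-rule expectancy update
#'
#' Only the chosen deck's expectancy moves toward the current utility:
#' `E_chosen <- E_chosen + a * (u - E_chosen)`.
#'
#' @inheritParams decay_update
#' @param a Learning rate, in (0, 1); 0 and 1 allowed for limiting analyses.
#' @return Updated 4-vector of expectancies.
#' @export
delta_update <- function(E, chosen, u, a) {
  stopifnot(length(E) == 4)
  j <- if (is.character(chosen)) deck_index(chosen) else as.integer(chosen)
  if (is.na(j) || j < 1L || j > 4L) abort("invalid deck")
  E[j] <- E[j] + a * (u - E[j])
  E
}

#' Choice sensitivity for the PVL models
#'
#' Maps consistency `c` to the trial-independent softmax sensitivity
#' `theta = 3^c - 1`, so `c = 0` yields uniform random choice and large
#' `c` near-deterministic choice.
#'
#' @param c Consistency, in \[0, 5\] (endpoints allowed for limits).
#' @return Sensitivity theta >= 0.
#' @export
choice_sensitivity_pvl <- function(c) 3^c - 1

#' Choice sensitivity for the EVL model
#'
#' The EVL sensitivity is trial-dependent: `theta(t) = (t / 10)^c`, so
#' choices become more (c > 0) or less (c < 0) deterministic as the task
#' progresses, and are constant when `c = 0`.
#'
#' @param c Consistency, in (-5, 5).
#' @param trial 1-based trial index (vectorized).
#' @return Sensitivities, same length as `trial`.
#' @export
choice_sensitivity_evl <- function(c, trial) {
  stopifnot(all(trial >= 1))
  (trial / 10)^c
}

#' Softmax choice probabilities over decks
#'
#' `p_j = exp(theta * E_j) / sum_k exp(theta * E_k)` over the available
#' decks; unavailable decks get probability zero. Computed with
#' max-subtraction so that `theta * E` of several hundred stays finite.
#'
#' @param E Numeric 4-vector of expectancies (order A, B, C, D).
#' @param theta Softmax sensitivity, >= 0.
#' @param available Character vector of available deck labels.
#' @return Named numeric 4-vector of probabilities summing to 1.
#' @examples
#' choice_probabilities(c(1, 0, 0, 0), theta = log(3))
#' @export
choice_probabilities <- function(E, theta, available = DECKS) {
  stopifnot(length(E) == 4, is.finite(theta), theta >= 0)
  if (length(available) == 0) abort("at least one deck must be available")
  idx <- deck_index(available)
  z <- theta * E[idx]
  z <- z - max(z)
  p <- exp(z) / sum(exp(z))
  out <- setNames(numeric(4), DECKS)
  out[idx] <- p
  out
}
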