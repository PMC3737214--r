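# Maximum-likelihood fitting on the latent (probit) scale: each parameter
# is lb + (ub - lb) * pnorm(z), and z is optimized unconstrained (boxed to
# [-8, 8] so pnorm stays away from exact 0/1), so estimates are strictly
# inside the bounds by construction.

#' @keywords internal
to_natural_vec <- function(z, info) {
  setNames(info$lb + (info$ub - info$lb) * pnorm(z), info$params)
}

#' Multistart maximum-likelihood fit of one session
#'
#' Optimizes [session_loglik()] over the latent scale from `n_starts`
#' Latin-hypercube starting points (deterministic given `seed`), keeping
#' the best optimum. Sessions shorter than 10 modeled trials are fit with
#' a warning.
#'
#' @param trials One subject's trial tibble.
#' @param model Model identifier.
#' @param n_starts Number of starts, default 10.
#' @param seed Seed for the start design, default 1.
#' @param horizon Modeling horizon; default from the depletion rule.
#' @return An `igt_mle`: parameter estimates (natural scale), log-likelihood
#'   at the optimum, convergence flag and bookkeeping.
#' @examples
#' s <- simulate_agent(pvl_params(0.3, 1.5, 0.6, 1.5), "pvl_decay", seed = 1)
#' fit <- fit_mle(s, "pvl_decay", n_starts = 5)
#' tidy(fit)
#' @export
fit_mle <- function(trials, model = "pvl_decay", n_starts = 10, seed = 1,
                    horizon = NULL) {
  info <- model_info(model)
  dat <- session_data(trials)
  horizon <- as.integer(horizon %||% truncate_at_depletion(DECKS[dat$deck + 1L]))
  if (horizon < 1) abort("session has no trials to model")
  if (horizon < 10)
    warn(paste0("modeling horizon is only ", horizon,
                " trials; estimates will be unstable"))
  K <- length(info$params)
  negll <- function(z) {
    -session_loglik_cpp(dat$deck, dat$win, dat$loss, horizon,
                        unname(to_natural_vec(z, info)), info$code)
  }
  # screen a larger Latin-hypercube design and optimize from the most
  # promising points; basin coverage at the cost of a few evaluations
  n_screen <- max(4L * n_starts, 40L)
  cand <- withr::with_seed(seed, qnorm(lhs::randomLHS(n_screen, K)))
  screen <- apply(cand, 1, negll)
  starts <- cand[order(screen)[seq_len(n_starts)], , drop = FALSE]
  best <- NULL
  n_ok <- 0L
  for (i in seq_len(n_starts)) {
    fit <- tryCatch(
      optim(starts[i, ], negll, method = "L-BFGS-B",
            lower = rep(-8, K), upper = rep(8, K)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (fit$convergence == 0) n_ok <- n_ok + 1L
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) {
    warn("all optimization starts failed; returning start-point evaluation")
    z <- starts[1, ]
    best <- list(par = z, value = negll(z), convergence = 1L)
  }
  structure(list(
    model = info$model,
    params = to_natural_vec(best$par, info),
    latent = setNames(best$par, info$params),
    loglik = -best$value,
    horizon = horizon, k = K, n_starts = n_starts,
    converged = n_ok > 0
  ), class = "igt_mle")
}

#' @export
print.igt_mle <- function(x, ...) {
  cat("<igt_mle> model =", x$model, " logLik =", round(x$loglik, 3),
      " horizon =", x$horizon, "\n")
  print(round(x$params, 4))
  invisible(x)
}

#' @rdname fit_mle
#' @param x An `igt_mle`.
#' @param ... Unused.
#' @export
tidy.igt_mle <- function(x, ...) {
  tibble::tibble(term = names(x$params), estimate = unname(x$params))
}

#' @rdname fit_mle
#' @export
glance.igt_mle <- function(x, ...) {
  tibble::tibble(
    model = x$model, logLik = x$loglik, k = x$k, horizon = x$horizon,
    BIC = x$k * log(x$horizon) - 2 * x$loglik,
    converged = x$converged, n_starts = x$n_starts
  )
}

#' Per-subject maximum-likelihood fits for a cohort
#'
#' @param x Cohort or labeled trials tibble.
#' @inheritParams fit_mle
#' @return Tibble with one row per subject: identifiers, parameter
#'   estimates, `loglik`, `horizon`, `bic`, `log_loss` (mean one-step-ahead
#'   negative log predictive probability per trial) and `converged`.
#' @export
fit_mle_cohort <- function(x, model = "pvl_decay", n_starts = 10, seed = 1) {
  trials <- cohort_trials(x)
  ids <- unique(trials$subject_id)
  purrr::imap_dfr(setNames(ids, ids), function(sid, nm) {
    st <- trials[trials$subject_id == sid, ]
    fit <- fit_mle(st, model, n_starts = n_starts,
                   seed = seed + match(sid, ids))
    tibble::tibble(
      subject_id = sid,
      group = if ("group" %in% names(st)) st$group[1] else NA_character_,
      !!!as.list(fit$params),
      loglik = fit$loglik, horizon = fit$horizon, k = fit$k,
      bic = fit$k * log(fit$horizon) - 2 * fit$loglik,
      log_loss = -fit$loglik / fit$horizon,
      converged = fit$converged
    )
  })
}
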