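# Independent reference implementations used as oracles. These are coded
# from the model definitions with plain base R, deliberately sharing no
# code with the package internals.

# Naive per-trial loop log-likelihood for all three models.
naive_loglik <- function(deck, win, loss, params, model, horizon = length(deck)) {
  E <- c(A = 0, B = 0, C = 0, D = 0)
  ll <- 0
  for (t in seq_len(horizon)) {
    theta <- switch(model,
      evl = (t / 10)^params[["c"]],
      3^params[["c"]] - 1
    )
    te <- theta * E
    lse <- max(te) + log(sum(exp(te - max(te))))
    ll <- ll + te[[deck[t]]] - lse
    if (model == "evl") {
      u <- (1 - params[["w"]]) * win[t] - params[["w"]] * abs(loss[t])
      E[deck[t]] <- E[deck[t]] + params[["phi"]] * (u - E[deck[t]])
    } else {
      x <- win[t] + loss[t]
      u <- if (x >= 0) x^params[["alpha"]] else
        -params[["lambda"]] * abs(x)^params[["alpha"]]
      if (model == "pvl_decay") {
        E <- params[["A"]] * E
        E[deck[t]] <- E[deck[t]] + u
      } else {
        E[deck[t]] <- E[deck[t]] + params[["A"]] * (u - E[deck[t]])
      }
    }
  }
  ll
}

# Exhaustive shortest-window HDI search.
brute_hdi <- function(draws, mass = 0.95) {
  x <- sort(draws)
  n <- length(x)
  m <- ceiling(mass * n)
  best <- c(-Inf, Inf)
  for (i in 1:(n - m + 1)) {
    if (x[i + m - 1] - x[i] < best[2] - best[1]) best <- c(x[i], x[i + m - 1])
  }
  best
}

# Random in-bounds parameters, kept away from the exact bounds.
rand_params <- function(model) {
  if (model == "evl") {
    c(w = runif(1, .05, .95), phi = runif(1, .05, .95), c = runif(1, -3, 3))
  } else {
    c(alpha = runif(1, .05, .95), lambda = runif(1, .1, 4.5),
      A = runif(1, .05, .95), c = runif(1, .05, 2))
  }
}

# A random session with realistic outcome magnitudes (not schedule-bound).
rand_session <- function(n = 60) {
  tibble::tibble(
    subject_id = "X1",
    trial = seq_len(n),
    deck = sample(c("A", "B", "C", "D"), n, replace = TRUE),
    win = sample(c(45, 50, 55, 90, 100, 110), n, replace = TRUE),
    loss = -sample(c(0, 0, 0, 25, 50, 150, 250, 1250), n, replace = TRUE)
  )
}

preset_generating_means <- function() {
  tibble::tibble(
    group = rep(c("HIV+/DU+", "HIV+/DU-", "HIV-/DU+", "HIV-/DU-"), each = 4),
    parameter = rep(c("alpha", "lambda", "A", "c"), times = 4),
    gen = c(.38, .06, .20, .49,
            .26, .25, .50, .55,
            .36, .07, .21, .62,
            .18, 1.84, .64, .36)
  )
}
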