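test_that("session log-likelihood matches the naive loop oracle", {
  withr::with_seed(7, {
    for (i in 1:35) {
      for (model in igt_models()) {
        s <- rand_session(n = sample(20:100, 1))
        params <- rand_params(model)
        got <- session_loglik(s, params, model, horizon = nrow(s))
        want <- naive_loglik(s$deck, s$win, s$loss, params, model)
        expect_equal(got, want, tolerance = 1e-10)
        expect_lte(got, 0)
      }
    }
  })
})

test_that("closed forms hold at the random-choice and one-trial limits", {
  s <- withr::with_seed(1, rand_session(100))
  ll <- session_loglik(s, c(alpha = .3, lambda = 1, A = .5, c = 1e-14),
                       "pvl_decay", horizon = 100)
  expect_equal(ll, 100 * log(0.25), tolerance = 1e-8)
  s1 <- s[1, ]
  expect_equal(session_loglik(s1, pvl_params(.4, 2, .6, 3), "pvl_decay"),
               log(0.25))
  expect_equal(session_loglik(s1, evl_params(.4, .2, 1), "evl"), log(0.25))
})

test_that("likelihood is equivariant under deck relabeling", {
  perm <- c(A = "C", B = "D", C = "B", D = "A")
  withr::with_seed(11, {
    for (model in igt_models()) {
      s <- rand_session(80)
      params <- rand_params(model)
      s2 <- s
      s2$deck <- unname(perm[s$deck])
      expect_equal(session_loglik(s, params, model, horizon = 80),
                   session_loglik(s2, params, model, horizon = 80),
                   tolerance = 1e-12)
    }
  })
})

test_that("decay at A -> 0 keeps only the most recent outcome per deck", {
  s <- withr::with_seed(3, rand_session(50))
  params <- c(alpha = .5, lambda = 1.5, A = 1e-12, c = 1)
  got <- session_loglik(s, params, "pvl_decay", horizon = 50)
  # oracle: expectancies manually zeroed each step except the chosen deck
  E <- c(A = 0, B = 0, C = 0, D = 0); ll <- 0; theta <- 3^1 - 1
  for (t in 1:50) {
    p <- exp(theta * E - max(theta * E)); p <- p / sum(p)
    ll <- ll + log(p[[s$deck[t]]])
    x <- s$win[t] + s$loss[t]
    u <- if (x >= 0) x^.5 else -1.5 * sqrt(abs(x))
    E[] <- 0; E[s$deck[t]] <- u
  }
  expect_equal(got, ll, tolerance = 1e-6)
})

test_that("depletion truncation retains the depleting trial and drops the rest", {
  expect_equal(truncate_at_depletion(character(0)), 0L)
  expect_equal(truncate_at_depletion(rep(c("A", "B", "C", "D"), 25)), 100L)
  deck <- c(rep("B", 59), rep("A", 25), "B", rep("C", 15))
  expect_equal(truncate_at_depletion(deck), 85L)
  s <- tibble::tibble(subject_id = "s", trial = seq_along(deck), deck = deck,
                      win = 50, loss = 0)
  expect_equal(truncate_at_depletion(s), 85L)
})

test_that("simulation is seed-reproducible and respects deck capacity", {
  p <- pvl_params(.4, .5, .3, 2)
  s1 <- simulate_agent(p, "pvl_decay", n_trials = 100, seed = 99)
  s2 <- simulate_agent(p, "pvl_decay", n_trials = 100, seed = 99)
  expect_identical(s1, s2)
  s3 <- simulate_agent(p, "pvl_decay", n_trials = 100, seed = 100)
  expect_false(identical(s1, s3))
  long <- simulate_agent(p, "pvl_decay", n_trials = 240, seed = 5)
  expect_true(all(table(long$deck) <= 60))
  expect_error(simulate_agent(p, "pvl_decay", n_trials = 241, seed = 1),
               "240")
})

test_that("a zero-consistency agent chooses uniformly", {
  p <- c(alpha = .4, lambda = 1, A = .5, c = 1e-14)
  pooled <- withr::with_seed(21, {
    do.call(rbind, lapply(1:100, function(i)
      simulate_agent(p, "pvl_decay", n_trials = 100, seed = 1000 + i)))
  })
  prop <- deck_proportions(pooled)$prop
  se <- sqrt(0.25 * 0.75 / nrow(pooled))
  expect_true(all(abs(prop - 0.25) < 3 * se))
})

test_that("loss-averse agents avoid the disadvantageous decks more", {
  # individual agents lock onto decks, so per-agent proportions are very
  # dispersed; 300 agents per arm keep the directional contrast many
  # standard errors wide
  sched <- payoff_schedule()
  prop_bad <- function(lam, seed) {
    mean(vapply(1:300, function(i) {
      s <- simulate_agent(c(alpha = .3, lambda = lam, A = .5, c = .5),
                          "pvl_decay", sched, n_trials = 100, seed = seed + i)
      mean(s$deck %in% c("A", "B"))
    }, numeric(1)))
  }
  expect_lt(prop_bad(4.5, 12000), prop_bad(0.06, 11000))
})
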