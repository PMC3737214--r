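mk_session <- function(decks, sid = "s1", group = "g") {
  tibble::tibble(subject_id = sid, group = group,
                 trial = seq_along(decks), deck = decks, win = 50, loss = 0)
}

test_that("net scores count advantageous minus disadvantageous picks", {
  all_good <- mk_session(rep(c("C", "D"), 10))
  expect_equal(net_scores(all_good)$net_score, 20)
  balanced <- mk_session(c(rep("A", 5), rep("B", 5), rep("C", 5), rep("D", 5)))
  expect_equal(net_scores(balanced)$net_score, 0)
  mixed <- mk_session(c(rep("A", 7), rep("B", 5), rep("C", 4), rep("D", 4)))
  expect_equal(net_scores(mixed)$net_score, -4)
  expect_error(net_scores(mk_session(character(0))), "empty")
})

test_that("blocks partition the session and scores stay in range", {
  s <- simulate_agent(pvl_params(.3, 1.5, .6, 1), "pvl_decay",
                      n_trials = 100, seed = 19)
  ns <- net_scores(s, block_size = 20)
  expect_equal(ns$block, 1:5)
  expect_equal(ns$n_trials, rep(20L, 5))
  expect_true(all(abs(ns$net_score) <= 20))
  # per-block scores sum to the whole-session net preference
  total <- sum(s$deck %in% c("C", "D")) - sum(s$deck %in% c("A", "B"))
  expect_equal(sum(ns$net_score), total)
  # partial final block reported separately
  ns7 <- net_scores(s[1:70, ], block_size = 20)
  expect_equal(ns7$n_trials, c(20L, 20L, 20L, 10L))
})

test_that("deck proportions count all trials and sum to one", {
  expect_equal(deck_proportions(mk_session(rep("B", 30)))$prop, c(0, 1, 0, 0))
  bal <- mk_session(rep(c("A", "B", "C", "D"), 25))
  expect_equal(deck_proportions(bal)$prop, rep(0.25, 4))
  s <- simulate_agent(pvl_params(.3, 1.5, .6, 1), "pvl_decay",
                      n_trials = 100, seed = 20)
  dp <- deck_proportions(s)
  expect_equal(sum(dp$prop), 1, tolerance = 1e-12)
  shuffled <- s[withr::with_seed(1, sample(nrow(s))), ]
  expect_equal(deck_proportions(shuffled), dp)
  expect_error(deck_proportions(s[0, ]), "empty")
})

test_that("group summary reduces correctly in degenerate cases", {
  one <- mk_session(rep(c("C", "A"), 10), sid = "a", group = "g1")
  clone <- mk_session(rep(c("C", "A"), 10), sid = "b", group = "g1")
  single <- mk_session(rep("D", 20), sid = "c", group = "g2")
  summ <- group_behavior_summary(rbind(one, clone, single), block_size = 20)
  g1 <- summ$overall[summ$overall$group == "g1", ]
  expect_equal(g1$sd, 0)
  expect_equal(g1$mean, 0)
  g2 <- summ$overall[summ$overall$group == "g2", ]
  expect_equal(g2$mean, 20)
  props <- summ$deck_proportions
  expect_equal(props$prop[props$group == "g2" & props$deck == "D"], 1)
})

test_that("less loss-averse cohorts favor deck B more", {
  prop_b <- function(lam, seed) {
    trials <- do.call(rbind, lapply(1:300, function(i)
      simulate_agent(c(alpha = .3, lambda = lam, A = .5, c = .5), "pvl_decay",
                     n_trials = 100, seed = seed + i,
                     subject_id = paste0("s", i))))
    dp <- deck_proportions(trials)
    dp$prop[dp$deck == "B"]
  }
  expect_gt(prop_b(0.06, 9000), prop_b(4.5, 9500))
})
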