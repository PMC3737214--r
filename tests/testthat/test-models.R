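test_that("prospect utility matches hand-computed values and is monotone", {
  expect_equal(prospect_utility(0, 0.5, 2), 0)
  expect_equal(prospect_utility(100, 0.5, 2), 10)
  expect_equal(prospect_utility(-100, 0.5, 2), -20)
  x <- seq(-300, 300, by = 7)
  u <- prospect_utility(x, 0.4, 1.7)
  expect_true(all(diff(u) > 0))
  expect_equal(sign(u), sign(x))
  # more loss-averse values never raise the utility of a loss
  for (x_neg in c(-10, -150, -1250)) {
    u_l <- prospect_utility(x_neg, 0.6, c(0.5, 1, 2, 4))
    expect_true(all(diff(u_l) < 0))
  }
  # alpha -> 1 makes utility linear
  expect_equal(prospect_utility(c(50, -80), 1 - 1e-12, 1), c(50, -80),
               tolerance = 1e-6)
})

test_that("EVL valence is the attention-weighted win/loss combination", {
  expect_equal(evl_valence(100, -250, 0.5), -75)
  expect_equal(evl_valence(100, -250, 0), 100)
  expect_equal(evl_valence(100, -250, 1), -250)
})

test_that("decay and delta updates follow their learning rules", {
  expect_equal(decay_update(c(0, 0, 0, 0), "B", 10, 0.5), c(0, 10, 0, 0))
  expect_equal(decay_update(c(1, 1, 1, 1), "A", 2, 0.5), c(2.5, 0.5, 0.5, 0.5))
  expect_equal(decay_update(c(3, 1, 4, 1), "C", 7, 0), c(0, 0, 7, 0))
  expect_equal(delta_update(c(0, 0, 0, 0), "C", 10, 0.1), c(0, 0, 1, 0))
  expect_equal(delta_update(c(2, 2, 2, 2), "D", 9, 1), c(2, 2, 2, 9))
  expect_equal(delta_update(c(2, 2, 2, 2), "D", 9, 0), c(2, 2, 2, 2))
  expect_error(decay_update(c(0, 0, 0, 0), "E", 1, 0.5), "deck")
  expect_error(delta_update(c(0, 0, 0, 0), 7, 1, 0.5), "deck")
})

test_that("choice sensitivities follow their stated mappings", {
  expect_equal(choice_sensitivity_pvl(0), 0)
  expect_equal(choice_sensitivity_pvl(1), 2)
  expect_equal(choice_sensitivity_pvl(3), 26)
  cs <- choice_sensitivity_pvl(seq(0, 5, by = 0.25))
  expect_true(all(diff(cs) > 0))
  expect_equal(choice_sensitivity_evl(0, 37), 1)
  expect_equal(choice_sensitivity_evl(2.3, 10), 1)
  expect_equal(choice_sensitivity_evl(1, 100), 10)
})

test_that("softmax probabilities are exact, normalized and stable", {
  expect_equal(unname(choice_probabilities(c(0, 0, 0, 0), 5)), rep(0.25, 4))
  expect_equal(unname(choice_probabilities(c(9, -3, 2, 0), 0)), rep(0.25, 4))
  p <- choice_probabilities(c(1, 0, 0, 0), log(3))
  expect_equal(unname(p), c(0.5, 1 / 6, 1 / 6, 1 / 6))
  withr::with_seed(42, {
    for (i in 1:50) {
      E <- rnorm(4, 0, 50)
      theta <- runif(1, 0, 30)
      p <- choice_probabilities(E, theta)
      expect_equal(sum(p), 1, tolerance = 1e-12)
      # invariance to a constant shift of all expectancies
      p2 <- choice_probabilities(E + rnorm(1, 0, 10), theta)
      expect_equal(p, p2, tolerance = 1e-9)
    }
  })
  # theta * E spanning +/- 700 must not overflow
  p <- choice_probabilities(c(700, -700, 0, 350), 1)
  expect_true(all(is.finite(p)))
  expect_equal(sum(p), 1, tolerance = 1e-12)
  # unavailable decks get zero mass
  p <- choice_probabilities(c(5, 1, 1, 1), 1, available = c("B", "C"))
  expect_equal(unname(p[c("A", "D")]), c(0, 0))
  expect_equal(sum(p), 1, tolerance = 1e-12)
  expect_error(choice_probabilities(c(0, 0, 0, 0), 1, available = character(0)),
               "available")
})

test_that("parameter constructors enforce open bounds", {
  expect_silent(pvl_params(0.5, 2.5, 0.5, 2.5))
  expect_error(pvl_params(0, 2.5, 0.5, 2.5), "out of bounds")
  expect_error(pvl_params(0.5, 5, 0.5, 2.5), "out of bounds")
  expect_error(evl_params(0.5, 0.5, 5), "out of bounds")
  expect_silent(evl_params(0.5, 0.5, -4.9))
})
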