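small_cohort <- function(seed = 17, n = 6,
                         means = c(alpha = .3, lambda = 1.2, A = .5, c = .8),
                         sds = c(alpha = .05, lambda = .3, A = .1, c = .2),
                         label = "g1") {
  g <- group_spec(label, n, means, sds, age_mean = 40, age_sd = 6)
  generate_cohort(study_design(list(g), seed = seed))
}

test_that("the sampler is reproducible from its seed", {
  cohort <- small_cohort()
  cfg <- mcmc_config(chains = 2, warmup = 100, draws = 100, seed = 5)
  f1 <- suppressWarnings(fit_hba(cohort, config = cfg))
  f2 <- suppressWarnings(fit_hba(cohort, config = cfg))
  expect_identical(f1$groups[[1]]$draws, f2$groups[[1]]$draws)
  f3 <- suppressWarnings(fit_hba(cohort, config = mcmc_config(
    chains = 2, warmup = 100, draws = 100, seed = 6)))
  expect_false(identical(f1$groups[[1]]$draws, f3$groups[[1]]$draws))
})

test_that("zero-heterogeneity groups pull subject estimates together", {
  cohort <- small_cohort(seed = 23, n = 8,
                         sds = c(alpha = 0, lambda = 0, A = 0, c = 0))
  fit <- suppressWarnings(fit_hba(cohort, config = mcmc_config(
    chains = 2, warmup = 300, draws = 300, seed = 11)))
  gf <- fit$groups[[1]]
  for (p in c("A", "lambda")) {
    qs <- paste0(gf$subjects, ".", p)
    post_mean <- vapply(qs, function(q) mean(gf$draws[, , q]), numeric(1))
    post_sd <- vapply(qs, function(q) sd(gf$draws[, , q]), numeric(1))
    truth <- cohort$subjects[[p]][1]
    expect_true(all(abs(post_mean - truth) < 3 * post_sd + 0.05))
    # shrinkage: subject posterior means spread less than their own
    # posterior uncertainty when the generator has no heterogeneity
    expect_lt(sd(post_mean), mean(post_sd))
  }
})

test_that("diagnostics cover every quantity and gate convergence", {
  cohort <- small_cohort(seed = 29, n = 5)
  fit <- suppressWarnings(fit_hba(cohort, config = mcmc_config(
    chains = 2, warmup = 150, draws = 150, seed = 2)))
  td <- tidy(fit)
  expect_true(all(is.finite(td$rhat)))
  expect_true(all(td$ess > 0))
  expect_setequal(
    td$quantity[grepl("^mu\\.", td$quantity)],
    paste0("mu.", c("alpha", "lambda", "A", "c")))
  expect_true(all(c("gm.alpha", "gm.lambda", "gm.A", "gm.c") %in% td$quantity))
  expect_identical(fit$converged, fit$max_rhat <= 1.1)
  gl <- glance(fit)
  expect_equal(gl$n_subjects, 5L)
})

test_that("the age covariate adds slope draws on every parameter", {
  cohort <- small_cohort(seed = 31, n = 6)
  fit <- suppressWarnings(fit_hba(cohort, config = mcmc_config(
    chains = 2, warmup = 150, draws = 150, seed = 3), covariate = "age"))
  qn <- dimnames(fit$groups[[1]]$draws)[[3]]
  expect_true(all(paste0("beta.", c("alpha", "lambda", "A", "c")) %in% qn))
  no_age <- small_cohort(seed = 31, n = 6)
  no_age$subjects$age <- NULL
  expect_error(fit_hba(no_age, config = mcmc_config(
    chains = 2, warmup = 50, draws = 50, seed = 1), covariate = "age"),
    "age")
})

test_that("group differences compare natural-scale group means", {
  g1 <- group_spec("hi", 8, c(alpha = .3, lambda = 2.5, A = .5, c = .8),
                   c(alpha = .03, lambda = .3, A = .1, c = .2))
  g2 <- group_spec("lo", 8, c(alpha = .3, lambda = .15, A = .5, c = .8),
                   c(alpha = .03, lambda = .05, A = .1, c = .2))
  cohort <- generate_cohort(study_design(list(g1, g2), seed = 41))
  fit <- suppressWarnings(fit_hba(cohort, config = mcmc_config(
    chains = 2, warmup = 250, draws = 250, seed = 13)))
  d <- group_difference(fit, "lambda", "hi", "lo")
  expect_gt(d$mean_diff, 0)
  expect_true(d$credible)
  expect_lte(d$hdi_low, d$hdi_high)
  same <- group_difference(fit, "lambda", "hi", "hi")
  expect_equal(c(same$mean_diff, same$hdi_low, same$hdi_high), c(0, 0, 0))
  expect_false(same$credible)
  expect_error(group_difference(fit, "lambda", "hi", "nope"), "unknown group")
  expect_error(group_difference(fit, "zeta", "hi", "lo"), "unknown parameter")
  all_d <- group_differences(fit)
  expect_equal(nrow(all_d), 4L)  # 1 pair x 4 parameters
  expect_true(all(all_d$hdi_low <= all_d$hdi_high))
})

test_that("groups need at least two subjects", {
  cohort <- small_cohort(seed = 43, n = 6)
  cohort$trials <- cohort$trials[cohort$trials$subject_id == "S01", ]
  cohort$subjects <- cohort$subjects[1, ]
  expect_error(fit_hba(cohort, config = mcmc_config(
    chains = 1, warmup = 50, draws = 50, seed = 1)), "fewer than 2")
})
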