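test_that("latent calibration reproduces natural-scale targets", {
  h <- latent_hyper <- igtrl:::latent_hyper
  for (case in list(c(.64, .18, 0, 1), c(1.84, .75, 0, 5),
                    c(.06, .01, 0, 5), c(.49, .40, 0, 5))) {
    lat <- h(case[1], case[2], case[3], case[4])
    z <- withr::with_seed(1, rnorm(2e5, lat$mu, lat$sigma))
    y <- case[3] + (case[4] - case[3]) * pnorm(z)
    expect_equal(mean(y), case[1], tolerance = 0.01)
    expect_equal(sd(y), case[2], tolerance = 0.02)
  }
  expect_error(h(0.5, 0.6, 0, 1), "unattainable")
  expect_error(h(1.2, 0.1, 0, 1), "inside")
})

test_that("preset draws match their stated group means within 5%", {
  for (spec in study_group_presets()) {
    big <- spec
    big$n <- 4000L
    draws <- sample_group_parameters(big, seed = 123)
    for (p in names(spec$param_means)) {
      expect_lt(abs(mean(draws[[p]]) - spec$param_means[[p]]),
                0.05 * spec$param_means[[p]] + 1e-8)
      lb <- igtrl:::model_info(spec$model)$lb[[p]]
      ub <- igtrl:::model_info(spec$model)$ub[[p]]
      expect_true(all(draws[[p]] > lb & draws[[p]] < ub))
    }
  }
})

test_that("zero hyper-SD collapses all subjects onto the hypermean", {
  spec <- group_spec("g", 8,
                     param_means = c(alpha = .3, lambda = 1.2, A = .5, c = .8),
                     param_sds = c(alpha = 0, lambda = 0, A = 0, c = 0))
  draws <- sample_group_parameters(spec, seed = 1)
  expect_equal(unname(apply(draws, 2, sd)), rep(0, 4))
  expect_equal(unname(colMeans(draws)),
               c(.3, 1.2, .5, .8), tolerance = 1e-12)
})

test_that("default design yields the four-group cohort structure", {
  cohort <- generate_cohort(default_study_design(seed = 4))
  expect_s3_class(cohort, "igt_cohort")
  sizes <- dplyr::count(cohort$subjects, group)
  expect_equal(sizes$n[match(c("HIV+/DU+", "HIV+/DU-", "HIV-/DU+", "HIV-/DU-"),
                             sizes$group)], c(14L, 17L, 14L, 12L))
  expect_equal(nrow(cohort$subjects), 57L)
  per <- dplyr::count(cohort$trials, subject_id)
  expect_true(all(per$n <= 100))
  picks <- dplyr::count(cohort$trials, subject_id, deck)
  expect_true(all(picks$n <= 60))
  expect_true(all(cohort$subjects$age >= 18 & cohort$subjects$age <= 80))
})

test_that("cohort generation is a pure function of design and seed", {
  d <- default_study_design(seed = 8)
  c1 <- generate_cohort(d)
  c2 <- generate_cohort(d)
  expect_identical(c1$trials, c2$trials)
  expect_identical(c1$subjects, c2$subjects)
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_cohort(c1, f1)
  write_cohort(c2, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("cohort CSV roundtrip preserves the data", {
  g <- study_group_presets()[[1]]
  g$n <- 4L
  cohort <- generate_cohort(study_design(list(g), seed = 3))
  tf <- withr::local_tempfile(fileext = ".csv")
  sf <- withr::local_tempfile(fileext = ".csv")
  write_cohort(cohort, tf, sf)
  back <- read_cohort(tf, sf)
  expect_equal(as.data.frame(back$trials), as.data.frame(cohort$trials))
  expect_equal(back$subjects$age, cohort$subjects$age)
})

test_that("malformed cohort files are rejected with row diagnostics", {
  tr <- tibble::tibble(subject_id = "s1", group = "g", trial = 1:3,
                       deck = c("A", "B", "E"), win = c(50, 50, 50), loss = 0)
  expect_error(as_igt_cohort(tr), "deck label 'E' at row 3")
  tr2 <- tibble::tibble(subject_id = "s1", group = "g",
                        trial = c(1, 2, 2), deck = "A",
                        win = 50, loss = 0)
  expect_error(as_igt_cohort(tr2), "duplicated \\(subject, trial\\)")
  tr3 <- tibble::tibble(subject_id = "s1", group = "g",
                        trial = c(1, 3, 4), deck = "A", win = 50, loss = 0)
  expect_error(as_igt_cohort(tr3), "not contiguous")
  tr4 <- tr3[0, ]
  f <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tibble::tibble(subject_id = "s", trial = 1), f)
  expect_error(suppressWarnings(read_cohort(f)), "missing column")
})

test_that("preset lambda gap shows up in subject-level MLE medians", {
  arm <- function(preset, seed) {
    g <- study_group_presets()[[preset]]
    g$n <- 50L
    cohort <- generate_cohort(study_design(list(g), seed = seed))
    fits <- fit_mle_cohort(cohort, "pvl_decay", n_starts = 6, seed = seed)
    median(fits$lambda)
  }
  expect_gt(arm("HIV-/DU-", 31), arm("HIV+/DU+", 32))
})
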