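# Latent (probit) hyperparameters from natural-scale targets -------------
#
# Subject parameters are bounded transforms of latent normals:
#   y = lb + (ub - lb) * pnorm(z),  z ~ N(mu, sigma^2).
# The population mean has the closed form
#   E[y] = lb + (ub - lb) * pnorm(mu / sqrt(1 + sigma^2)),
# and the SD is matched numerically (1-d quadrature + uniroot), so preset
# draws reproduce stated natural-scale means/SDs up to Monte-Carlo error.

#' Latent hyperparameters matching a natural-scale mean and SD
#'
#' @param mean,sd Target mean and SD of the parameter on its natural scale.
#' @param lb,ub Parameter bounds.
#' @return List with latent `mu` and `sigma`.
#' @keywords internal
latent_hyper <- function(mean, sd, lb = 0, ub = 1) {
  if (sd < 0) abort("hyper-SD must be >= 0")
  m <- (mean - lb) / (ub - lb)
  s <- sd / (ub - lb)
  if (m <= 0 || m >= 1)
    abort("target mean must lie strictly inside the parameter bounds")
  if (s == 0) return(list(mu = qnorm(m), sigma = 0))
  if (s^2 >= m * (1 - m))
    abort("target SD is unattainable for a bounded parameter with this mean")
  h <- qnorm(m)
  sd_of <- function(sigma) {
    mu <- h * sqrt(1 + sigma^2)
    e2 <- integrate(function(x) pnorm(x)^2 * dnorm(x, mu, sigma),
                    lower = mu - 10 * sigma, upper = mu + 10 * sigma,
                    rel.tol = 1e-10)$value
    sqrt(max(e2 - m^2, 0))
  }
  sigma <- uniroot(function(sg) sd_of(sg) - s, lower = 1e-6, upper = 25,
                   tol = 1e-9)$root
  list(mu = h * sqrt(1 + sigma^2), sigma = sigma)
}

#' Implied natural-scale population mean of a latent group level
#'
#' @param mu,sigma Latent hypermean and hyper-SD.
#' @param lb,ub Parameter bounds.
#' @return Population mean of the bounded transform.
#' @export
natural_group_mean <- function(mu, sigma, lb = 0, ub = 1) {
  lb + (ub - lb) * pnorm(mu / sqrt(1 + sigma^2))
}

# Group specification -----------------------------------------------------

#' Specify one group of a synthetic study design
#'
#' Targets are given on the natural parameter scale (the scale on which
#' group summaries are usually reported); the matching latent probit-scale
#' hyperparameters are computed internally.
#'
#' @param label Group label.
#' @param n Number of subjects, >= 1.
#' @param param_means,param_sds Named numeric vectors (all model
#'   parameters) of natural-scale means and SDs.
#' @param age_mean,age_sd Optional age distribution in years (normal,
#'   truncated to 18-80 when drawn).
#' @param model Generating model, default `"pvl_decay"`.
#' @return An `igt_group_spec`.
#' @examples
#' group_spec("controls", 12,
#'   param_means = c(alpha = .18, lambda = 1.84, A = .64, c = .36),
#'   param_sds   = c(alpha = .02, lambda = .75,  A = .18, c = .30))
#' @export
group_spec <- function(label, n, param_means, param_sds,
                       age_mean = NULL, age_sd = NULL,
                       model = "pvl_decay") {
  info <- model_info(model)
  if (n < 1) abort("group size `n` must be >= 1")
  param_means <- param_means[info$params]
  param_sds <- param_sds[info$params]
  if (anyNA(param_means) || anyNA(param_sds))
    abort(paste0("param_means and param_sds must name all of: ",
                 paste(info$params, collapse = ", ")))
  if (any(param_sds < 0)) abort("hyper-SDs must be >= 0")
  latent <- purrr::map(info$params, function(p) {
    latent_hyper(param_means[[p]], param_sds[[p]], info$lb[[p]], info$ub[[p]])
  })
  names(latent) <- info$params
  structure(list(
    label = label, n = as.integer(n), model = info$model,
    param_means = param_means, param_sds = param_sds,
    mu = purrr::map_dbl(latent, "mu"),
    sigma = purrr::map_dbl(latent, "sigma"),
    age_mean = age_mean, age_sd = age_sd
  ), class = "igt_group_spec")
}

#' Four-group study presets
#'
#' Group sizes (14/17/14/12), PVL-decay parameter means/SDs and age
#' distributions emulating a four-group HIV-serostatus by drug-use-history
#' cohort design. These presets define the default synthetic study
#' conditions used throughout the package.
#'
#' @return Named list of four [group_spec()] objects, in the order
#'   HIV+/DU+, HIV+/DU-, HIV-/DU+, HIV-/DU-.
#' @export
study_group_presets <- function() {
  tab <- list(
    `HIV+/DU+` = list(n = 14, age = c(43.3, 4.9),
      m = c(alpha = .38, lambda = .06, A = .20, c = .49),
      s = c(alpha = .04, lambda = .01, A = .04, c = .40)),
    `HIV+/DU-` = list(n = 17, age = c(38.8, 8.3),
      m = c(alpha = .26, lambda = .25, A = .50, c = .55),
      s = c(alpha = .02, lambda = .16, A = .19, c = .38)),
    `HIV-/DU+` = list(n = 14, age = c(40.6, 7.1),
      m = c(alpha = .36, lambda = .07, A = .21, c = .62),
      s = c(alpha = .03, lambda = .01, A = .06, c = .38)),
    `HIV-/DU-` = list(n = 12, age = c(33.5, 8.5),
      m = c(alpha = .18, lambda = 1.84, A = .64, c = .36),
      s = c(alpha = .02, lambda = .75, A = .18, c = .30))
  )
  purrr::imap(tab, function(g, label) {
    group_spec(label, g$n, g$m, g$s, age_mean = g$age[1], age_sd = g$age[2])
  })
}

#' Assemble a synthetic study design
#'
#' @param groups List of [group_spec()] objects.
#' @param n_trials Trials per subject (<= 100 are modeled as a four-deck
#'   task; default 100).
#' @param model Generating model identifier.
#' @param escalation_rate Payoff escalation per 10-card block.
#' @param seed Master seed; the whole cohort is a pure function of
#'   (design, seed). Per-subject session seeds are `seed + subject
#'   ordinal`.
#' @return An `igt_design`.
#' @export
study_design <- function(groups, n_trials = 100, model = "pvl_decay",
                         escalation_rate = 0.1, seed = 1) {
  stopifnot(length(groups) >= 1)
  labels <- purrr::map_chr(groups, "label")
  if (anyDuplicated(labels)) abort("group labels must be unique")
  structure(list(
    groups = groups, n_trials = as.integer(n_trials),
    model = model_info(model)$model,
    escalation_rate = escalation_rate, seed = as.integer(seed)
  ), class = "igt_design")
}

#' Default four-group study design
#'
#' [study_design()] over [study_group_presets()]: 57 subjects in groups of
#' 14/17/14/12, 100 trials each, PVL-decay generating model.
#'
#' @param seed Master seed (default 2013).
#' @inheritParams study_design
#' @return An `igt_design`.
#' @export
default_study_design <- function(seed = 2013, n_trials = 100) {
  study_design(study_group_presets(), n_trials = n_trials, seed = seed)
}

#' Draw subject-level parameters for one group
#'
#' Subject parameters are bounded probit transforms of latent normal
#' draws `z ~ N(mu_p, sigma_p)`, so every draw respects the model bounds
#' by construction, and with `sigma = 0` all subjects share the
#' back-transformed hypermean exactly.
#'
#' @param spec An [group_spec()].
#' @param seed Optional seed (caller RNG preserved).
#' @return Tibble of `spec$n` rows with one column per model parameter.
#' @export
sample_group_parameters <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "igt_group_spec"))
  if (!is.null(seed)) withr::local_seed(seed)
  info <- model_info(spec$model)
  draws <- purrr::map(info$params, function(p) {
    z <- rnorm(spec$n, spec$mu[[p]], spec$sigma[[p]])
    info$lb[[p]] + (info$ub[[p]] - info$lb[[p]]) * pnorm(z)
  })
  names(draws) <- info$params
  tibble::as_tibble(draws)
}

# Cohort container ---------------------------------------------------------

#' Bundle trials and subject metadata into a cohort
#'
#' @param trials Long trial tibble (`subject_id`, `group`, `trial`,
#'   `deck`, `win`, `loss`).
#' @param subjects Optional subject metadata tibble (`subject_id`,
#'   `group`, optionally `age` and generating parameters).
#' @param design Optional `igt_design` that produced the cohort.
#' @return An `igt_cohort` (list with `trials` and `subjects`).
#' @export
as_igt_cohort <- function(trials, subjects = NULL, design = NULL) {
  trials <- validate_cohort_trials(trials)
  if (is.null(subjects)) {
    subjects <- dplyr::distinct(trials, .data$subject_id, .data$group)
  }
  structure(list(trials = trials, subjects = subjects, design = design),
            class = "igt_cohort")
}

#' @export
print.igt_cohort <- function(x, ...) {
  cat("<igt_cohort> ", nrow(x$subjects), " subjects, ",
      nrow(x$trials), " trials, ",
      dplyr::n_distinct(x$subjects$group), " group(s)\n", sep = "")
  print(dplyr::count(x$subjects, .data$group))
  invisible(x)
}

#' @keywords internal
cohort_trials <- function(x) {
  if (inherits(x, "igt_cohort")) x$trials else {
    stopifnot(is.data.frame(x))
    x
  }
}

#' Generate a synthetic cohort from a study design
#'
#' Draws each group's subject parameters and ages under the master seed,
#' then simulates every subject's session with the design's generating
#' model; the session seed of subject `i` (cohort-wide ordinal) is
#' `design$seed + i`, making generation a pure function of the design.
#'
#' @param design An [study_design()].
#' @return An `igt_cohort`; `subjects` records group, age and the true
#'   generating parameters.
#' @examples
#' cohort <- generate_cohort(default_study_design(seed = 1))
#' cohort
#' @export
generate_cohort <- function(design) {
  stopifnot(inherits(design, "igt_design"))
  schedule <- payoff_schedule(design$escalation_rate)
  info <- model_info(design$model)
  withr::local_seed(design$seed)
  subj <- purrr::imap_dfr(design$groups, function(spec, nm) {
    pars <- sample_group_parameters(spec)
    age <- if (!is.null(spec$age_mean)) {
      a <- rnorm(spec$n, spec$age_mean, spec$age_sd)
      pmin(pmax(a, 18), 80)
    } else rep(NA_real_, spec$n)
    dplyr::bind_cols(tibble::tibble(group = spec$label, age = age), pars)
  })
  subj <- dplyr::mutate(subj,
    subject_id = sprintf("S%02d", dplyr::row_number()), .before = 1)
  trials <- purrr::pmap_dfr(
    list(seq_len(nrow(subj)), subj$subject_id, subj$group),
    function(i, sid, grp) {
      params <- unlist(subj[i, info$params])
      simulate_agent(params, design$model, schedule,
                     n_trials = design$n_trials, seed = design$seed + i,
                     subject_id = sid, group = grp)
    })
  as_igt_cohort(trials, subjects = subj, design = design)
}

#' Share of subjects that deplete a deck
#'
#' @param x Cohort or trials tibble.
#' @return Fraction of subjects whose modeling horizon is shorter than
#'   their session.
#' @export
depletion_rate <- function(x) {
  mean(modeling_horizons(x)$depleted)
}

# Cohort I/O ---------------------------------------------------------------

#' @keywords internal
validate_cohort_trials <- function(trials) {
  need <- c("subject_id", "group", "trial", "deck", "win", "loss")
  miss <- setdiff(need, names(trials))
  if (length(miss) > 0)
    abort(paste0("cohort is missing column(s): ", paste(miss, collapse = ", ")))
  bad_deck <- which(!trials$deck %in% DECKS)
  if (length(bad_deck) > 0)
    abort(paste0("unknown deck label '", trials$deck[bad_deck[1]],
                 "' at row ", bad_deck[1],
                 if (length(bad_deck) > 1)
                   paste0(" (and ", length(bad_deck) - 1, " more row(s))")
                 else ""))
  if (any(trials$win < 0) || any(trials$loss > 0))
    abort("wins must be >= 0 and losses <= 0")
  key <- paste(trials$subject_id, trials$trial)
  dup <- which(duplicated(key))
  if (length(dup) > 0)
    abort(paste0("duplicated (subject, trial) pair at row ", dup[1], ": ",
                 key[dup[1]]))
  chk <- trials |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::summarise(
      contiguous = all(sort(.data$trial) == seq_along(.data$trial)),
      n = dplyr::n(), .groups = "drop")
  if (any(!chk$contiguous)) {
    bad <- chk$subject_id[!chk$contiguous][1]
    abort(paste0("trial indices for subject '", bad,
                 "' are not contiguous starting at 1"))
  }
  over <- trials |>
    dplyr::count(.data$subject_id, .data$deck) |>
    dplyr::filter(.data$n > 60)
  if (nrow(over) > 0)
    abort(paste0("subject '", over$subject_id[1], "' chose deck ",
                 over$deck[1], " more than 60 times"))
  tibble::as_tibble(trials)
}

#' Write / read a cohort as CSV
#'
#' Trial CSV columns: `subject_id`, `group`, `trial`, `deck`, `win`,
#' `loss`. Subject metadata (group, age, generating parameters when
#' present) goes to a companion CSV. Reading validates deck labels,
#' duplicated (subject, trial) pairs and trial contiguity, reporting the
#' offending row.
#'
#' @param cohort An `igt_cohort` (or trials tibble for `write_cohort()`).
#' @param path Trials CSV path.
#' @param subjects_path Optional metadata CSV path.
#' @return `write_cohort()` the cohort invisibly; `read_cohort()` an
#'   `igt_cohort`.
#' @export
write_cohort <- function(cohort, path, subjects_path = NULL) {
  trials <- cohort_trials(cohort)
  readr::write_csv(trials, path)
  if (!is.null(subjects_path) && inherits(cohort, "igt_cohort"))
    readr::write_csv(cohort$subjects, subjects_path)
  invisible(cohort)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path, subjects_path = NULL) {
  trials <- readr::read_csv(path, col_types = readr::cols(
    subject_id = readr::col_character(), group = readr::col_character(),
    trial = readr::col_integer(), deck = readr::col_character(),
    win = readr::col_double(), loss = readr::col_double()
  ))
  subjects <- if (!is.null(subjects_path))
    readr::read_csv(subjects_path, show_col_types = FALSE)
  else NULL
  as_igt_cohort(trials, subjects = subjects)
}
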