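# Hierarchical Bayesian estimation. Each group is fit with its own
# hyperparameters: subject latent z[i, p] ~ N(mu_p (+ beta_p * age_i),
# sigma_p), parameters are bounded probit transforms of z, priors are
# mu_p, beta_p ~ N(0, 1) and sigma_p ~ half-normal(1). Sampling is
# Metropolis-within-Gibbs (compiled inner loop, R-side seeding), so the
# whole posterior is reproducible from the config seed.

#' MCMC configuration
#'
#' @param chains Number of chains (default 4).
#' @param warmup Warmup (adaptation) iterations per chain (default 1000).
#' @param draws Retained draws per chain (default 1000).
#' @param seed Sampler seed (chains are seeded deterministically from it).
#' @param n_sweeps Subject-level Metropolis sweeps per iteration
#'   (default 2; cheap insurance on mixing).
#' @param profile Optional shortcut: `"smoke"` = 2 chains x 200/200 (fast
#'   checks), `"full"` = 4 chains x 1000/1000.
#' @return An `igt_mcmc_config` list.
#' @export
mcmc_config <- function(chains = 4, warmup = 1000, draws = 1000, seed = 1,
                        n_sweeps = 2, profile = NULL) {
  if (!is.null(profile)) {
    profile <- match.arg(profile, c("smoke", "full"))
    if (profile == "smoke") {
      chains <- 2; warmup <- 200; draws <- 200
    } else {
      chains <- 4; warmup <- 1000; draws <- 1000
    }
  }
  stopifnot(chains >= 1, warmup >= 1, draws >= 2)
  structure(list(chains = as.integer(chains), warmup = as.integer(warmup),
                 draws = as.integer(draws), seed = as.integer(seed),
                 n_sweeps = as.integer(n_sweeps), profile = profile),
            class = "igt_mcmc_config")
}

#' Hierarchical Bayesian fit of a cohort
#'
#' Fits the chosen model to every group of the cohort independently (one
#' set of group-level hypermeans/SDs per group). With `covariate =
#' "age"`, a linear age slope on the standardized cohort age enters every
#' parameter's latent group mean. Split R-hat and effective sample size
#' are computed for every saved quantity; any R-hat above 1.1 flags the
#' fit as non-converged (with a warning, not an error).
#'
#' In addition to latent hypermeans (`mu.<param>`), hyper-SDs
#' (`sigma.<param>`), optional slopes (`beta.<param>`) and subject-level
#' natural-scale parameters (`<subject>.<param>`), the posterior carries
#' the derived natural-scale group mean `gm.<param>` =
#' `lb + (ub - lb) * pnorm(mu / sqrt(1 + sigma^2))`, the population mean
#' implied by the latent hyperparameters; group comparisons use it.
#'
#' @param x An `igt_cohort` (or labeled trials tibble).
#' @param model Model identifier, default `"pvl_decay"`.
#' @param config An [mcmc_config()].
#' @param covariate `NULL` or `"age"` (requires subject ages).
#' @return An `igt_hba` object; see [tidy.igt_hba()], [group_difference()],
#'   [hba_param_table()].
#' @examples
#' \donttest{
#' cohort <- generate_cohort(default_study_design(seed = 1))
#' fit <- fit_hba(cohort, config = mcmc_config(profile = "smoke"))
#' hba_param_table(fit)
#' }
#' @export
fit_hba <- function(x, model = "pvl_decay", config = mcmc_config(),
                    covariate = NULL) {
  info <- model_info(model)
  trials <- cohort_trials(x)
  if (!"group" %in% names(trials)) abort("trials must carry a `group` label")
  use_age <- !is.null(covariate)
  if (use_age && !identical(covariate, "age"))
    abort("`covariate` must be NULL or \"age\"")
  subjects <- if (inherits(x, "igt_cohort")) x$subjects else
    dplyr::distinct(trials, .data$subject_id, .data$group)
  if (use_age) {
    if (!"age" %in% names(subjects) || anyNA(subjects$age))
      abort("covariate = \"age\" requires an age for every subject")
    subjects$age_std <- (subjects$age - mean(subjects$age)) / sd(subjects$age)
  }
  groups <- unique(subjects$group)
  K <- length(info$params)
  fits <- purrr::imap(setNames(groups, groups), function(g, nm) {
    ids <- subjects$subject_id[subjects$group == g]
    if (length(ids) < 2) abort(paste0("group '", g, "' has fewer than 2 subjects"))
    dat <- purrr::map(ids, function(sid) {
      st <- trials[trials$subject_id == sid, ]
      d <- session_data(st)
      h <- truncate_at_depletion(DECKS[d$deck + 1L])
      if (h < 1) abort(paste0("subject '", sid, "' has no trials"))
      c(d, list(horizon = h))
    })
    age <- if (use_age) subjects$age_std[match(ids, subjects$subject_id)]
           else numeric(0)
    g_idx <- match(g, groups)
    qn <- c(paste0("mu.", info$params), paste0("sigma.", info$params),
            if (use_age) paste0("beta.", info$params),
            as.vector(t(outer(ids, info$params, paste, sep = "."))))
    draws <- array(NA_real_,
                   dim = c(config$draws, config$chains, length(qn)),
                   dimnames = list(NULL, NULL, qn))
    for (ch in seq_len(config$chains)) {
      set.seed(config$seed + 104729L * g_idx + ch)
      z_init <- matrix(rnorm(length(ids) * K, 0, 0.5), nrow = length(ids))
      draws[, ch, ] <- run_chain_cpp(
        purrr::map(dat, "deck"), purrr::map(dat, "win"),
        purrr::map(dat, "loss"),
        as.integer(purrr::map_int(dat, "horizon")), info$code,
        unname(info$lb), unname(info$ub), age, use_age,
        config$warmup, config$draws, config$n_sweeps, z_init)
    }
    # derived natural-scale group means
    gm <- array(NA_real_, dim = c(config$draws, config$chains, K),
                dimnames = list(NULL, NULL, paste0("gm.", info$params)))
    for (p in seq_len(K)) {
      mu <- draws[, , paste0("mu.", info$params[p]), drop = FALSE]
      sg <- draws[, , paste0("sigma.", info$params[p]), drop = FALSE]
      gm[, , p] <- info$lb[p] + (info$ub[p] - info$lb[p]) *
        pnorm(mu / sqrt(1 + sg^2))
    }
    all_draws <- array(c(draws, gm),
                       dim = c(config$draws, config$chains, length(qn) + K),
                       dimnames = list(NULL, NULL, c(qn, dimnames(gm)[[3]])))
    diag <- purrr::map_dfr(dimnames(all_draws)[[3]], function(q) {
      m <- all_draws[, , q]
      if (config$chains == 1) m <- matrix(m, ncol = 1)
      v <- as.vector(m)
      hdi <- compute_hdi(v)
      tibble::tibble(quantity = q, mean = mean(v), sd = sd(v),
                     hdi_low = hdi$low, hdi_high = hdi$high,
                     rhat = split_rhat(m), ess = ess_basic(m))
    })
    list(group = g, subjects = ids, draws = all_draws, diagnostics = diag)
  })
  max_rhat <- max(purrr::map_dbl(fits, ~ max(.x$diagnostics$rhat, na.rm = TRUE)))
  converged <- is.finite(max_rhat) && max_rhat <= 1.1
  if (!converged)
    warn(paste0("MCMC may not have converged: max split R-hat = ",
                round(max_rhat, 3), " (> 1.1)"))
  structure(list(model = info$model, info = info, covariate = covariate,
                 config = config, groups = fits, max_rhat = max_rhat,
                 converged = converged),
            class = "igt_hba")
}

#' @export
print.igt_hba <- function(x, ...) {
  cat("<igt_hba> model =", x$model, "|", length(x$groups), "group(s) |",
      x$config$chains, "chains x", x$config$draws, "draws | max R-hat =",
      round(x$max_rhat, 3), if (!x$converged) "(NOT CONVERGED)" else "", "\n")
  print(hba_param_table(x))
  invisible(x)
}

#' Posterior draws of the natural-scale group mean
#'
#' @param fit An `igt_hba`.
#' @param param Parameter name.
#' @param group Group label.
#' @return Numeric vector of draws (all chains pooled).
#' @export
group_mean_draws <- function(fit, param, group) {
  stopifnot(inherits(fit, "igt_hba"))
  if (!group %in% names(fit$groups)) abort(paste0("unknown group: ", group))
  if (!param %in% fit$info$params) abort(paste0("unknown parameter: ", param))
  as.vector(fit$groups[[group]]$draws[, , paste0("gm.", param)])
}

#' Group mean (SD) table of posterior parameter estimates
#'
#' For every group and parameter: the mean and SD, across subjects, of
#' the subject-level posterior means (natural scale) - the conventional
#' "group summary" layout for this model family.
#'
#' @param fit An `igt_hba`.
#' @return Tibble: `group`, `parameter`, `mean`, `sd`, `n`.
#' @export
hba_param_table <- function(fit) {
  stopifnot(inherits(fit, "igt_hba"))
  purrr::imap_dfr(fit$groups, function(gf, g) {
    purrr::map_dfr(fit$info$params, function(p) {
      qs <- paste0(gf$subjects, ".", p)
      pm <- purrr::map_dbl(qs, ~ mean(gf$draws[, , .x]))
      tibble::tibble(group = g, parameter = p, mean = mean(pm),
                     sd = sd(pm), n = length(pm))
    })
  })
}

#' @rdname fit_hba
#' @param x An `igt_hba`.
#' @param ... Unused.
#' @export
tidy.igt_hba <- function(x, ...) {
  purrr::imap_dfr(x$groups, function(gf, g) {
    dplyr::mutate(gf$diagnostics, group = g, .before = 1)
  })
}

#' @rdname fit_hba
#' @export
glance.igt_hba <- function(x, ...) {
  tibble::tibble(
    model = x$model, n_groups = length(x$groups),
    n_subjects = sum(purrr::map_int(x$groups, ~ length(.x$subjects))),
    chains = x$config$chains, draws_per_chain = x$config$draws,
    covariate = x$covariate %||% "none",
    max_rhat = x$max_rhat, converged = x$converged
  )
}

#' Export posterior draws and summaries
#'
#' @param fit An `igt_hba`.
#' @param draws_path Optional CSV path for long-format draws
#'   (`group`, `chain`, `iter`, `quantity`, `value`).
#' @param summary_path Optional JSON path for per-quantity summaries
#'   (mean, SD, 95% HDI, R-hat, ESS).
#' @return The fit, invisibly.
#' @export
export_posterior <- function(fit, draws_path = NULL, summary_path = NULL) {
  stopifnot(inherits(fit, "igt_hba"))
  if (!is.null(draws_path)) {
    long <- purrr::imap_dfr(fit$groups, function(gf, g) {
      d <- gf$draws
      tidyr::expand_grid(iter = seq_len(dim(d)[1]),
                         chain = seq_len(dim(d)[2]),
                         quantity = dimnames(d)[[3]]) |>
        dplyr::mutate(group = g,
                      value = d[cbind(.data$iter, .data$chain,
                                      match(.data$quantity,
                                            dimnames(d)[[3]]))]) |>
        dplyr::select("group", "chain", "iter", "quantity", "value")
    })
    readr::write_csv(long, draws_path)
  }
  if (!is.null(summary_path)) {
    jsonlite::write_json(tidy(fit), summary_path, digits = NA,
                         auto_unbox = TRUE)
  }
  invisible(fit)
}

# Diagnostics --------------------------------------------------------------

# Split R-hat: each chain is halved, and the usual potential-scale-
# reduction factor is computed over the 2 * chains half-sequences.
#' @keywords internal
split_rhat <- function(draws) {
  if (is.null(dim(draws))) draws <- matrix(draws, ncol = 1)
  n <- nrow(draws)
  half <- floor(n / 2)
  seqs <- do.call(cbind, purrr::map(seq_len(ncol(draws)), function(ch) {
    cbind(draws[1:half, ch], draws[(n - half + 1):n, ch])
  }))
  W <- mean(apply(seqs, 2, var))
  B <- half * var(colMeans(seqs))
  if (!is.finite(W) || W <= .Machine$double.eps) return(1)
  sqrt(((half - 1) / half * W + B / half) / W)
}

# Effective sample size via chain-averaged autocorrelations truncated by
# Geyer's initial positive-pair rule.
#' @keywords internal
ess_basic <- function(draws) {
  if (is.null(dim(draws))) draws <- matrix(draws, ncol = 1)
  n <- nrow(draws)
  m <- ncol(draws)
  if (all(apply(draws, 2, var) <= .Machine$double.eps)) return(n * m)
  max_lag <- min(n - 1, 200)
  rho <- rowMeans(apply(draws, 2, function(x) {
    if (var(x) <= .Machine$double.eps) rep(0, max_lag + 1)
    else as.vector(acf(x, lag.max = max_lag, plot = FALSE)$acf)
  }))
  s <- 0
  t <- 2
  while (t + 1 <= length(rho)) {
    pair <- rho[t] + rho[t + 1]
    if (!is.finite(pair) || pair < 0) break
    s <- s + pair
    t <- t + 2
  }
  max(m * n / (1 + 2 * s), 1)
}
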