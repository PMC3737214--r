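#' Compare candidate models on a cohort
#'
#' Every model is fit to every subject by multistart maximum likelihood;
#' models are ranked by the summed per-subject BIC
#' (`k * log(horizon) - 2 * loglik`), with the mean one-step-ahead
#' predictive log-loss per trial reported as a secondary short-term
#' prediction criterion. The selected model attains the lowest summed
#' BIC.
#'
#' @param x Cohort or trials tibble.
#' @param models Character vector of model identifiers (>= 1).
#' @param n_starts Multistart count per subject fit.
#' @param seed Seed for the start designs.
#' @return An `igt_model_comparison`: `summary` tibble (per model:
#'   `total_bic`, `mean_log_loss`, `selected`), per-subject `fits`, and
#'   `selected`.
#' @examples
#' \donttest{
#' cohort <- generate_cohort(default_study_design(seed = 1))
#' cmp <- compare_models(cohort, n_starts = 5)
#' tidy(cmp)
#' }
#' @export
compare_models <- function(x, models = igt_models(), n_starts = 10,
                           seed = 1) {
  if (length(models) < 1) abort("`models` must list at least one model")
  models <- vapply(models, function(m) model_info(m)$model, character(1))
  fits <- purrr::map(setNames(models, models), function(m) {
    fit_mle_cohort(x, model = m, n_starts = n_starts, seed = seed)
  })
  summary <- purrr::imap_dfr(fits, function(f, m) {
    tibble::tibble(
      model = m, k = f$k[1], n_subjects = nrow(f),
      total_bic = sum(f$bic), mean_log_loss = mean(f$log_loss)
    )
  })
  summary$selected <- summary$total_bic == min(summary$total_bic)
  structure(list(summary = summary, fits = fits,
                 selected = summary$model[which.min(summary$total_bic)]),
            class = "igt_model_comparison")
}

#' @export
print.igt_model_comparison <- function(x, ...) {
  cat("Model comparison (summed per-subject BIC; lower is better)\n")
  print(x$summary)
  cat("Selected:", x$selected, "\n")
  invisible(x)
}

#' @rdname compare_models
#' @export
tidy.igt_model_comparison <- function(x, ...) x$summary

#' @rdname compare_models
#' @export
glance.igt_model_comparison <- function(x, ...) {
  tibble::tibble(
    selected = x$selected,
    n_models = nrow(x$summary),
    n_subjects = x$summary$n_subjects[1],
    bic_margin = sort(x$summary$total_bic)[2] - min(x$summary$total_bic)
  )
}
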