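#' Credible group difference in a model parameter
#'
#' Computes the posterior of the difference in the natural-scale group
#' mean (`gm.<param>` draws, group A minus group B) draw by draw, its
#' mean and 95% HDI, and the credible-difference decision: the groups are
#' credibly different when the HDI excludes zero.
#'
#' @param fit An `igt_hba` covering both groups.
#' @param param Parameter name (e.g. `"lambda"`).
#' @param group_a,group_b Group labels.
#' @param mass HDI mass, default 0.95.
#' @return Tibble: `parameter`, `group_a`, `group_b`, `mean_diff`,
#'   `hdi_low`, `hdi_high`, `mass`, `credible`.
#' @export
group_difference <- function(fit, param, group_a, group_b, mass = 0.95) {
  a <- group_mean_draws(fit, param, group_a)
  b <- group_mean_draws(fit, param, group_b)
  d <- a - b
  if (identical(group_a, group_b)) {
    return(tibble::tibble(parameter = param, group_a = group_a,
                          group_b = group_b, mean_diff = 0, hdi_low = 0,
                          hdi_high = 0, mass = mass, credible = FALSE))
  }
  hdi <- compute_hdi(d, mass = mass)
  tibble::tibble(
    parameter = param, group_a = group_a, group_b = group_b,
    mean_diff = mean(d), hdi_low = hdi$low, hdi_high = hdi$high,
    mass = mass, credible = hdi$low > 0 || hdi$high < 0
  )
}

#' All pairwise group differences
#'
#' @param fit An `igt_hba`.
#' @param params Parameters to compare; default all model parameters.
#' @param mass HDI mass.
#' @return Tibble of [group_difference()] rows for every unordered group
#'   pair and parameter.
#' @export
group_differences <- function(fit, params = NULL, mass = 0.95) {
  stopifnot(inherits(fit, "igt_hba"))
  params <- params %||% fit$info$params
  groups <- names(fit$groups)
  if (length(groups) < 2) abort("need at least two groups")
  pairs <- combn(groups, 2, simplify = FALSE)
  purrr::map_dfr(params, function(p) {
    purrr::map_dfr(pairs, function(pr) {
      group_difference(fit, p, pr[1], pr[2], mass = mass)
    })
  })
}
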