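#' Highest density interval of a sample
#'
#' The HDI is the shortest contiguous interval containing at least `mass`
#' of the draws: over the sorted sample, every window of
#' `ceiling(mass * n)` consecutive draws is a candidate and the narrowest
#' one (first, on ties) is returned.
#'
#' @param draws Numeric vector of at least 2 finite draws.
#' @param mass Probability mass, in (0, 1); default 0.95.
#' @return Tibble with `low`, `high`, `mass`.
#' @examples
#' compute_hdi(rnorm(10000), mass = 0.95)
#' @export
compute_hdi <- function(draws, mass = 0.95) {
  draws <- as.numeric(draws)
  if (length(draws) < 2) abort("at least 2 draws are required")
  if (any(!is.finite(draws))) abort("draws must be finite")
  if (!is.numeric(mass) || mass <= 0 || mass >= 1)
    abort("`mass` must be in (0, 1)")
  x <- sort(draws)
  n <- length(x)
  m <- ceiling(mass * n)
  if (m >= n) return(tibble::tibble(low = x[1], high = x[n], mass = mass))
  widths <- x[m:n] - x[1:(n - m + 1)]
  i <- which.min(widths)
  tibble::tibble(low = x[i], high = x[i + m - 1], mass = mass)
}
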