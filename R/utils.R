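#' Log-odds transform with boundary clipping
#'
#' Computes `log(p / (1 - p))` after clipping `p` into
#' `[epsilon, 1 - epsilon]`, so that probabilities at or numerically
#' indistinguishable from 0 or 1 (e.g. softmax underflow) map to large but
#' finite log-odds.
#'
#' @param p Numeric vector of probabilities in `[0, 1]`.
#' @param epsilon Clipping bound; default `1e-12`.
#' @return Numeric vector of log-odds.
#' @examples
#' logit(c(0.5, 0.75))
#' logit(1) # finite
#' @export
logit <- function(p, epsilon = 1e-12) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    abort("`p` must lie in [0, 1].", class = "pulvalidate_argument_error")
  }
  p <- pmin(pmax(p, epsilon), 1 - epsilon)
  log(p / (1 - p))
}

#' Inverse logit
#' @param x Numeric vector of log-odds.
#' @return Probabilities in (0, 1).
#' @export
inv_logit <- function(x) {
  stats::plogis(x)
}

#' Wilson score confidence interval for a binomial proportion
#'
#' The Wilson interval behaves sensibly at the boundaries (proportions of 0
#' or 1 still get informative intervals inside `[0, 1]`), which matters for
#' sensitivities near 100%.
#'
#' @param x Number of successes (vectorised).
#' @param n Number of trials.
#' @param level Confidence level, default 0.95.
#' @return A tibble with columns `estimate`, `conf.low`, `conf.high`.
#' @export
wilson_ci <- function(x, n, level = 0.95) {
  stopifnot(all(x >= 0), all(n > 0), all(x <= n))
  z <- qnorm(1 - (1 - level) / 2)
  phat <- x / n
  denom <- 1 + z^2 / n
  centre <- (phat + z^2 / (2 * n)) / denom
  half <- z * sqrt(phat * (1 - phat) / n + z^2 / (4 * n^2)) / denom
  tibble::tibble(
    estimate = phat,
    conf.low = pmin(pmax(0, centre - half), phat),
    conf.high = pmax(pmin(1, centre + half), phat)
  )
}

# Numerically stable softmax over rows of a matrix of linear predictors.
softmax_rows <- function(eta) {
  m <- apply(eta, 1L, max)
  ex <- exp(eta - m)
  ex / rowSums(ex)
}

# shared enumerations
pul_outcome_levels <- c("failed_pul", "iup", "ep", "ppul", "gtd", "lost")
pul_analysis_outcomes <- c("failed_pul", "iup", "ep", "ppul")
pul_type_levels <- c("true_pul", "probable_iup", "probable_ep")
interval_bin_levels <- c("lt24", "24-39", "40-56", "57-72", "gt72")
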