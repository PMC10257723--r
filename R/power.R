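#' Power of the two-sample proportions test
#'
#' Classical normal-approximation power for comparing two proportions with a
#' pooled-variance null (the model behind `stats::power.prop.test`). Used to
#' ask how large a cohort must be before a 90% reduction in homozygote
#' frequency (`p2 = 0.1 * p1`) is detectable.
#'
#' @param p1,p2 True proportions in the two groups, `0 < p2 < p1 < 1`.
#' @param n_per_group Sample size per group (may be fractional).
#' @param alpha Two-sided significance level; default 0.05.
#' @return Power of the two-sided test (probability of rejecting in the
#'   direction of the true difference).
#' @export
power_two_proportions <- function(p1, p2, n_per_group, alpha = 0.05) {
  if (any(p1 <= 0) || any(p1 >= 1) || any(p2 <= 0) || any(p2 >= 1)) {
    stop("proportions must lie strictly inside (0, 1)", call. = FALSE)
  }
  stopifnot(all(n_per_group > 0), alpha > 0, alpha < 1)
  pbar <- (p1 + p2) / 2
  qbar <- 1 - pbar
  d <- abs(p1 - p2)
  z <- stats::qnorm(1 - alpha / 2)
  stats::pnorm((sqrt(n_per_group) * d - z * sqrt(2 * pbar * qbar)) /
                 sqrt(p1 * (1 - p1) + p2 * (1 - p2)))
}

#' Sample size for the two-sample proportions test
#'
#' Numerically inverts [power_two_proportions()] in `n` (monotone bisection).
#'
#' @inheritParams power_two_proportions
#' @param power Target power, in `(alpha, 1)`.
#' @param tol Bisection tolerance on power; default 1e-9.
#' @return Continuous per-group sample size achieving the target power.
#' @export
solve_n_two_proportions <- function(p1, p2, alpha = 0.05, power = 0.8,
                                    tol = 1e-9) {
  stopifnot(power > 0, power < 1)
  lo <- 1
  hi <- 2
  while (power_two_proportions(p1, p2, hi, alpha) < power) {
    hi <- hi * 2
    if (hi > 1e15) stop("required sample size out of range", call. = FALSE)
  }
  while (hi - lo > max(1e-8, lo * 1e-12)) {
    mid <- (lo + hi) / 2
    if (power_two_proportions(p1, p2, mid, alpha) < power) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}
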