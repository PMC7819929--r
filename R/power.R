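#' Cohen's effect size w for chi-square-family tests
#'
#' \deqn{w = \sqrt{\sum_c (p^{alt}_c - p^{null}_c)^2 / p^{null}_c}}
#' the discrepancy between two category distributions on the scale used for
#' chi-square power analysis.
#'
#' @param p_null null category distribution (strictly positive, sums to 1).
#' @param p_alt alternative category distribution (sums to 1).
#' @return nonnegative scalar.
#' @export
effect_size_w <- function(p_null, p_alt) {
  if (length(p_null) != length(p_alt))
    stop("distributions must have the same number of categories")
  if (abs(sum(p_null) - 1) > 1e-8 || abs(sum(p_alt) - 1) > 1e-8)
    stop("distributions must sum to 1")
  if (any(p_null <= 0))
    stop("p_null must be strictly positive in every category")
  sqrt(sum((p_alt - p_null)^2 / p_null))
}

#' Power of a chi-square test via the noncentral distribution
#'
#' For a test with `df` degrees of freedom at level `alpha` and a true effect
#' of size `w` observed over `N` independent observations, the test statistic
#' is asymptotically noncentral chi-square with noncentrality
#' \eqn{\lambda = N w^2}; power is the probability of exceeding the central
#' critical value.  For the multinomial analyses of the source-monitoring
#' designs, `N` is the number of participants times the number of test
#' items.
#'
#' @param w Cohen's effect size (>= 0).
#' @param N total observation count.
#' @param df positive integer degrees of freedom.
#' @param alpha test level in (0, 1).
#' @return list with `power`, `lambda`, `critical_value`.
#' @export
power_chisq <- function(w, N, df = 1, alpha = 0.05) {
  stopifnot(w >= 0, N > 0, alpha > 0, alpha < 1)
  if (df <= 0) stop("df must be a positive integer")
  lambda <- N * w^2
  crit <- stats::qchisq(1 - alpha, df)
  list(power = stats::pchisq(crit, df, ncp = lambda, lower.tail = FALSE),
       lambda = lambda, critical_value = crit)
}

#' Minimum detectable effect size
#'
#' The smallest Cohen's w whose [power_chisq()] reaches `power_target`,
#' found by bisection (power is monotone increasing in w).
#'
#' @param power_target target power in (alpha, 1).
#' @inheritParams power_chisq
#' @param tol bisection tolerance on w.
#' @return scalar w.
#' @export
min_detectable_w <- function(power_target, N, df = 1, alpha = 0.05,
                             tol = 1e-6) {
  stopifnot(power_target > alpha, power_target < 1)
  lo <- 0; hi <- 1
  while (power_chisq(hi, N, df, alpha)$power < power_target) hi <- hi * 2
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (power_chisq(mid, N, df, alpha)$power >= power_target) hi <- mid
    else lo <- mid
  }
  hi
}

#' Design power statement for an experiment
#'
#' The prospective sensitivity of a design for the guessing-parameter tests:
#' power to detect a small effect (w = 0.03 by convention) in a 1-df
#' multinomial test with N = participants x test items.
#'
#' @param n_participants sample size.
#' @param n_items number of items in the memory test per participant.
#' @param w effect size.
#' @param df test degrees of freedom.
#' @param alpha test level.
#' @return list from [power_chisq()] plus the inputs.
#' @export
design_power <- function(n_participants, n_items, w = 0.03, df = 1,
                         alpha = 0.05) {
  N <- n_participants * n_items
  c(power_chisq(w, N, df, alpha),
    list(w = w, N = N, n_participants = n_participants, n_items = n_items,
         df = df, alpha = alpha))
}
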