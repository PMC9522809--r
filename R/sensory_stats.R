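# Duo-trio sensory panel statistics: exact right-tailed one-proportion
# binomial test (appropriate at panel sizes of ~20) and the
# normal-approximation z statistic, both against a chance rate p0 = 0.5.

validate_binomial_args <- function(k, n, p0) {
  stopifnot(length(k) == 1L, length(n) == 1L, length(p0) == 1L)
  if (is.na(k) || is.na(n) || is.na(p0) ||
      k != round(k) || n != round(n) || n < 1 || k < 0 || k > n)
    stop("need integers 0 <= k <= n with n >= 1 (got k = ", k,
         ", n = ", n, ")")
  if (p0 <= 0 || p0 >= 1) stop("p0 must lie strictly between 0 and 1")
}

#' Exact right-tailed binomial probability
#'
#' `P(X >= k)` for `X ~ Binomial(n, p0)`: the exact p-value of the
#' right-tailed one-proportion test used for duo-trio panels, where under
#' the null the panelist picks the matching sample by chance (`p0 = 0.5`).
#' Computed as an explicit sum of binomial terms for `n <= 64` and by a
#' log-sum-exp of log binomial coefficients for larger `n`.
#'
#' @param k Number of correct responses (successes), `0 <= k <= n`.
#' @param n Number of panelists (trials).
#' @param p0 Null success probability in (0, 1) (default 0.5).
#' @return The upper-tail probability in \[0, 1\].
#' @examples
#' binomial_right_tail(16, 21)  # 0.0133018
#' @export
binomial_right_tail <- function(k, n, p0 = 0.5) {
  validate_binomial_args(k, n, p0)
  if (k == 0) return(1)
  i <- k:n
  if (n <= 64) {
    p <- sum(choose(n, i) * p0^i * (1 - p0)^(n - i))
  } else {
    lt <- lchoose(n, i) + i * log(p0) + (n - i) * log1p(-p0)
    m <- max(lt)
    p <- exp(m) * sum(exp(lt - m))
  }
  min(p, 1)
}

#' Normal-approximation z statistic for a proportion
#'
#' `z = (k - n p0) / sqrt(n p0 (1 - p0))`, with no continuity correction.
#'
#' @inheritParams binomial_right_tail
#' @return The z statistic.
#' @examples
#' z_statistic(4, 21)  # -2.84 to 2 d.p.
#' @export
z_statistic <- function(k, n, p0 = 0.5) {
  validate_binomial_args(k, n, p0)
  v <- n * p0 * (1 - p0)
  if (v <= 0) stop("degenerate binomial variance")
  (k - n * p0) / sqrt(v)
}

#' Duo-trio panel test report
#'
#' Assembles the z statistic, the exact right-tailed p-value and the
#' reject/fail-to-reject verdict at level `alpha` for a duo-trio result
#' in which `k` of `n` panelists correctly matched the reference sample.
#'
#' @inheritParams binomial_right_tail
#' @param alpha Significance level (default 0.05).
#' @return An object of class `duo_trio_result` with fields `n_panelists`,
#'   `n_correct`, `p0`, `z`, `p_value`, `alpha`, `reject`.
#' @examples
#' duo_trio_test(16, 21)  # significant: p = 0.0133 < 0.05
#' @export
duo_trio_test <- function(k, n, p0 = 0.5, alpha = 0.05) {
  stopifnot(alpha > 0, alpha < 1)
  p <- binomial_right_tail(k, n, p0)
  structure(list(n_panelists = as.integer(n), n_correct = as.integer(k),
                 p0 = p0, z = z_statistic(k, n, p0), p_value = p,
                 alpha = alpha, reject = p < alpha),
            class = "duo_trio_result")
}

#' @export
print.duo_trio_result <- function(x, ...) {
  cat("Duo-trio one-proportion binomial test (right-tailed)\n")
  cat(sprintf("  correct: %d / %d   null p0: %g\n",
              x$n_correct, x$n_panelists, x$p0))
  cat(sprintf("  Z statistic: %.2f   exact p value: %.7g\n", x$z, x$p_value))
  cat(if (x$reject)
        sprintf("  p < alpha = %g: reject the chance-level null\n", x$alpha)
      else
        sprintf("  p >= alpha = %g: cannot reject the chance-level null\n",
                x$alpha))
  invisible(x)
}
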