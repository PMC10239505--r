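#' Storey q-values for false discovery rate control
#'
#' Computes q-values from two-tailed p-values using Storey's procedure:
#' the proportion of true nulls \eqn{\pi_0} is estimated by evaluating
#' \eqn{\hat\pi_0(\lambda) = \#\{p > \lambda\} / (m(1-\lambda))} on the
#' grid \eqn{\lambda = 0.05, 0.10, \dots, 0.95}, smoothing with a cubic
#' spline (df = 3) and taking the smoothed value at \eqn{\lambda = 0.95},
#' clipped to (0, 1]. Then
#' \eqn{q_i = \min_{p_j \ge p_i} \hat\pi_0\, m\, p_j / \mathrm{rank}(p_j)},
#' which is monotone in p. With \eqn{\pi_0} fixed at 1 the result equals
#' the Benjamini-Hochberg adjusted p-values exactly.
#'
#' With fewer than 20 tests the \eqn{\pi_0} estimator is too unstable and
#' \eqn{\pi_0} is fixed to 1 (a message is emitted).
#'
#' @param p vector of p-values in (0, 1].
#' @param pi0 optional fixed \eqn{\pi_0} overriding the estimator.
#' @param lambda tuning grid for the \eqn{\pi_0} estimator.
#' @param smooth_df spline degrees of freedom.
#' @return numeric vector of q-values, same order as \code{p}, with the
#'   estimated \eqn{\pi_0} in attribute \code{"pi0"}.
#' @export
qvalues <- function(p, pi0 = NULL, lambda = seq(0.05, 0.95, by = 0.05),
                    smooth_df = 3) {
  .assert(is.numeric(p) && length(p) >= 1, "p must be a numeric vector")
  .assert(all(p > 0 & p <= 1), "p-values must lie in (0, 1]")
  m <- length(p)
  if (is.null(pi0)) {
    if (m < 20) {
      message("fewer than 20 tests: pi0 fixed to 1 (BH-equivalent)")
      pi0 <- 1
    } else {
      pi0_l <- vapply(lambda, function(l) mean(p > l) / (1 - l), 0)
      sp <- stats::smooth.spline(lambda, pi0_l, df = smooth_df)
      pi0 <- stats::predict(sp, x = max(lambda))$y
      pi0 <- min(max(pi0, 1e-8), 1)
    }
  } else {
    .assert(pi0 > 0 && pi0 <= 1, "pi0 must lie in (0, 1]")
  }
  o <- order(p, decreasing = TRUE)
  q <- pi0 * m * p[o] / (m:1)
  q <- pmin(1, cummin(q))
  out <- numeric(m)
  out[o] <- q
  attr(out, "pi0") <- pi0
  out
}
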