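# Wilson score interval for a binomial proportion.

#' Wilson score confidence interval
#'
#' Score-test inversion interval for a binomial proportion: centre
#' \eqn{(\hat p + z^2/2n) / (1 + z^2/n)}, half-width
#' \eqn{z \sqrt{\hat p (1-\hat p)/n + z^2/4n^2} / (1 + z^2/n)},
#' clipped to \[0, 1\]. Well-behaved at 0 and 1: for zero events the
#' upper bound is exactly \eqn{z^2 / (n + z^2)}.
#'
#' @param successes Event count, 0 <= successes <= n.
#' @param n Number of trials (>= 1).
#' @param confidence Confidence level (default 0.95).
#' @return Named numeric: `lower`, `upper`.
#' @export
#' @examples
#' wilsonInterval(0, 231)    # upper bound 0.02 at two decimals
#' wilsonInterval(5, 10)
wilsonInterval <- function(successes, n, confidence = 0.95) {
  if (n < 1) stop("n must be >= 1")
  stopifnot(successes >= 0, successes <= n)
  z <- stats::qnorm(1 - (1 - confidence) / 2)
  p <- successes / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  c(lower = max(0, centre - half), upper = min(1, centre + half))
}
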