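#' Draw from a normal distribution truncated below
#'
#' Inverse-CDF sampler for \eqn{N(\mu, \sigma^2)} restricted to
#' `[lower, Inf)`. Allelic-frequency noise cannot be negative, so every
#' stochastic frequency in this package is drawn through this function with
#' `lower = 0`.
#'
#' @param n Number of draws.
#' @param mean,sd Parameters of the parent normal. `sd = 0` returns `mean`
#'   repeated (a point mass), without division.
#' @param lower Truncation point (default 0).
#' @return Numeric vector of length `n`, all values `>= lower`.
#' @keywords internal
rtruncnorm0 <- function(n, mean, sd, lower = 0) {
  stopifnot(n >= 0, all(sd >= 0))
  mean <- rep_len(mean, n)
  sd <- rep_len(sd, n)
  out <- pmax(mean, lower) # sd = 0: point mass, no division
  pos <- sd > 0
  if (any(pos)) {
    p0 <- stats::pnorm(lower, mean[pos], sd[pos])
    u <- stats::runif(sum(pos), p0, 1)
    # pmax guards against u numerically hitting p0 from below
    out[pos] <- pmax(stats::qnorm(u, mean[pos], sd[pos]), lower)
  }
  out
}

#' Moments of a normal distribution truncated below
#'
#' Closed-form mean and standard deviation of \eqn{N(\mu, \sigma^2)}
#' restricted to `[lower, Inf)`. Used as the independent oracle when
#' checking that [fit_background()] recovers the parameters of simulated
#' reference replicates.
#'
#' @inheritParams rtruncnorm0
#' @return A list with elements `mean` and `sd`.
#' @examples
#' truncnorm_moments(0.065, 0.062)  # background noise after truncation at 0
#' @export
truncnorm_moments <- function(mean, sd, lower = 0) {
  stopifnot(sd >= 0)
  if (sd == 0) {
    return(list(mean = max(mean, lower), sd = 0))
  }
  alpha <- (lower - mean) / sd
  lambda <- stats::dnorm(alpha) / (1 - stats::pnorm(alpha))
  m <- mean + sd * lambda
  v <- sd^2 * (1 + alpha * lambda - lambda^2)
  list(mean = m, sd = sqrt(max(v, 0)))
}
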