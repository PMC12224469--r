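#' Inverse-Gaussian waiting-time density of the heartbeat model
#'
#' Density of the waiting time since the last heartbeat event,
#' \deqn{f(t \mid u_k) = \sqrt{\frac{\xi_0}{2\pi (t-u_k)^3}}
#'   \exp\!\left\{-\frac{1}{2}\,
#'   \frac{\xi_0 (t-u_k-\mu)^2}{\mu^2 (t-u_k)}\right\},}
#' the renewal density at the core of the point-process heart-rate model.
#'
#' @param t Evaluation time(s) (s), strictly greater than `u_k`.
#' @param u_k Time of the last event (s).  Default 0 gives the density of
#'   the elapsed interval directly.
#' @param mu Mean heart period \eqn{\mu > 0} (s).
#' @param xi0 Shape parameter \eqn{\xi_0 > 0} (s).
#' @param log If `TRUE`, return the log-density.
#' @return Density value(s); variance of the distribution is
#'   \eqn{\mu^3/\xi_0}.
#' @export
ig_pdf <- function(t, u_k = 0, mu, xi0, log = FALSE) {
  if (any(mu <= 0) || any(xi0 <= 0))
    stop("`mu` and `xi0` must be positive", call. = FALSE)
  w <- t - u_k
  if (any(w <= 0)) stop("`t` must be strictly greater than `u_k`", call. = FALSE)
  ll <- 0.5 * (base::log(xi0) - base::log(2 * pi) - 3 * base::log(w)) -
    0.5 * xi0 * (w - mu)^2 / (mu^2 * w)
  if (log) ll else exp(ll)
}

#' Inverse-Gaussian cumulative distribution and survival
#'
#' @param q Elapsed time(s) since the last event (s), > 0.
#' @param mu Mean (s), > 0.
#' @param xi0 Shape (s), > 0.
#' @param lower.tail If `FALSE`, the survival function.
#' @param log.p If `TRUE`, log-probability (computed stably; used for the
#'   right-censoring term of the local likelihood).
#' @return Probability (or log-probability).
#' @export
ig_cdf <- function(q, mu, xi0, lower.tail = TRUE, log.p = FALSE) {
  if (any(mu <= 0) || any(xi0 <= 0))
    stop("`mu` and `xi0` must be positive", call. = FALSE)
  if (any(q <= 0)) stop("`q` must be positive", call. = FALSE)
  s <- sqrt(xi0 / q)
  z1 <- s * (q / mu - 1)
  z2 <- s * (q / mu + 1)
  if (lower.tail && !log.p) {
    p <- stats::pnorm(z1) + exp(2 * xi0 / mu + stats::pnorm(-z2, log.p = TRUE))
    return(pmin(p, 1))
  }
  # log-survival: S = Phi(-z1) - exp(2*xi0/mu) * Phi(-z2), both terms tiny or
  # near-cancelling for q >> mu, so assemble in log space
  t1 <- stats::pnorm(-z1, log.p = TRUE)
  t2 <- 2 * xi0 / mu + stats::pnorm(-z2, log.p = TRUE)
  logS <- t1 + log1p(-pmin(exp(t2 - t1), 1 - 1e-16))
  if (lower.tail) {
    p <- -expm1(logS)  # 1 - S
    if (log.p) base::log(p) else p
  } else {
    if (log.p) logS else exp(logS)
  }
}

#' Sample inverse-Gaussian waiting times
#'
#' Transformation sampler (chi-square of a standard normal plus a
#' Bernoulli choice between conjugate roots).
#'
#' @param n Number of draws.
#' @param mu Mean (s), > 0.
#' @param xi0 Shape (s), > 0.
#' @return Numeric vector of positive draws with mean `mu` and variance
#'   `mu^3 / xi0`.
#' @export
ig_sample <- function(n, mu, xi0) {
  if (any(mu <= 0) || any(xi0 <= 0))
    stop("`mu` and `xi0` must be positive", call. = FALSE)
  y <- stats::rnorm(n)^2
  x <- mu + mu^2 * y / (2 * xi0) -
    mu / (2 * xi0) * sqrt(4 * mu * xi0 * y + mu^2 * y^2)
  swap <- stats::runif(n) >= mu / (mu + x)
  x[swap] <- mu^2 / x[swap]
  x
}
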