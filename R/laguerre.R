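#' Discrete-time orthonormal Laguerre basis
#'
#' Constructs the configuration of the discrete-time orthonormal Laguerre
#' functions used to compress long autoregressive heartbeat memory into a
#' small number of coefficients.  The j-th basis function is
#' \deqn{\phi_j(n) = \alpha^{(n-j)/2} (1-\alpha)^{1/2}
#'   \sum_{i=0}^{j} (-1)^i \binom{n}{i} \binom{j}{i}
#'   \alpha^{j-i} (1-\alpha)^{i},}
#' which is orthonormal on the non-negative integers:
#' \eqn{\sum_n \phi_i(n)\phi_j(n) = \delta_{ij}}.
#'
#' @param alpha Geometric decay parameter, in (0, 1).  Smaller values give
#'   faster-decaying memory.  Default 0.2.
#' @param J_max Highest basis order (orders run 0..J_max).  Default 9.
#' @param N_max Truncation length of the convolution, in lags (beats).
#'   Contributions beyond 200 lags are below 1e-10 at alpha = 0.2.
#' @return An object of class `laguerre_basis`: a list with `alpha`,
#'   `J_max`, `N_max` and `Phi`, the `N_max x (J_max+1)` matrix of
#'   \eqn{\phi_j(n)} evaluated at lags n = 1..N_max.
#' @seealso [laguerre_phi()], [laguerre_outputs()]
#' @export
#' @examples
#' b <- laguerre_basis(alpha = 0.2, J_max = 9)
#' # columns are orthonormal (over lags 0..N): Gram matrix ~ identity
#' G <- crossprod(laguerre_matrix(b, n_lags = 2000))
#' max(abs(G - diag(10)))
laguerre_basis <- function(alpha = 0.2, J_max = 9, N_max = 200) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1)
    stop("`alpha` must be a single number in (0, 1)", call. = FALSE)
  if (J_max < 0 || N_max < J_max + 1)
    stop("need J_max >= 0 and N_max > J_max", call. = FALSE)
  # rows cover lags 0..N_max-1: the filter weights the most recent
  # completed interval by phi_j(0), preserving the orthonormality (and
  # hence identifiability) of the expansion
  Phi <- laguerre_matrix(list(alpha = alpha, J_max = J_max),
                         n_lags = N_max - 1L)
  structure(list(alpha = alpha, J_max = as.integer(J_max),
                 N_max = as.integer(N_max), Phi = Phi),
            class = "laguerre_basis")
}

#' Evaluate a single orthonormal Laguerre function
#'
#' @param basis A [laguerre_basis()] (only `alpha` and `J_max` are used).
#' @param j Basis order, 0 <= j <= J_max.
#' @param n Lag(s), non-negative integers; vectorised over `n`.
#' @return \eqn{\phi_j(n)}, finite for all valid inputs.
#' @export
laguerre_phi <- function(basis, j, n) {
  alpha <- basis$alpha
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)", call. = FALSE)
  if (j < 0 || j > basis$J_max) stop("order `j` out of range", call. = FALSE)
  if (any(n < 0)) stop("lag `n` must be non-negative", call. = FALSE)
  vapply(n, function(nn) {
    i <- 0:j
    s <- sum((-1)^i * choose(nn, i) * choose(j, i) *
               alpha^(j - i) * (1 - alpha)^i)
    alpha^((nn - j) / 2) * sqrt(1 - alpha) * s
  }, numeric(1))
}

#' Laguerre basis matrix over a lag range
#'
#' @param basis A `laguerre_basis` (or list with `alpha`, `J_max`).
#' @param n_lags Number of lags; rows cover n = 0..n_lags.
#' @return Matrix of size `(n_lags + 1) x (J_max + 1)`, column j+1 holding
#'   \eqn{\phi_j(n)}.
#' @export
laguerre_matrix <- function(basis, n_lags) {
  J <- basis$J_max
  n <- 0:n_lags
  out <- matrix(0, length(n), J + 1L)
  for (j in 0:J) {
    out[, j + 1L] <- laguerre_phi(basis, j, n)
  }
  colnames(out) <- paste0("phi", 0:J)
  out
}

#' Laguerre filter outputs of a heart-period history
#'
#' Computes the vector \eqn{l_j(t) = \sum_{n \ge 0} \phi_j(n)\,
#' HP_{\tilde N(t) - n}} where \eqn{\tilde N(t) = \max\{k : u_k < t\}} is
#' the index of the last event strictly before `t` (left-open convention),
#' so the output depends only on intervals fully observed before `t`; the
#' most recent completed interval carries weight \eqn{\phi_j(0)}, which
#' keeps the expansion orthonormal over the lags actually used.
#'
#' @param ev An [event_series()].
#' @param basis A [laguerre_basis()].
#' @param t Evaluation time (s), scalar.
#' @return Numeric vector of length `J_max + 1` with names `l0..lJ`.
#' @export
laguerre_outputs <- function(ev, basis, t) {
  u <- ev$u
  Ntil <- sum(u < t)
  # HP_k defined for k >= 2; need at least J_max+1 of them strictly before t
  if (Ntil - 1L < basis$J_max + 1L)
    stop("insufficient heart-period history before t", call. = FALSE)
  hp <- c(NA_real_, diff(u))
  n_lags <- min(Ntil - 1L, basis$N_max)  # lags 0..n_lags-1
  h <- hp[Ntil - (seq_len(n_lags) - 1L)] # HP_{Ntil}, HP_{Ntil-1}, ...
  l <- drop(crossprod(basis$Phi[seq_len(n_lags), , drop = FALSE], h))
  names(l) <- paste0("l", 0:basis$J_max)
  l
}
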