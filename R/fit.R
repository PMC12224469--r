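#' Fit the inverse-Gaussian point-process heart-rate model
#'
#' Fits, on a sliding window, the inhomogeneous point-process model in
#' which the waiting time to the next heartbeat is inverse-Gaussian with
#' history-dependent mean
#' \deqn{\mu_{HP}(t) = g_0(t) + \sum_{j=0}^{P_p} g_1(j,t)\, l_j(t),}
#' where \eqn{l_j(t)} are orthonormal Laguerre filter outputs of the past
#' heart periods.  At every grid time `t` (spacing `step`) the parameter
#' vector \eqn{\xi(t) = \{g_0, g_1, \xi_0\}} maximises the local
#' log-likelihood of the intervals observed in \eqn{[t-W, t]} (plus a
#' right-censoring term for the interval ongoing at `t`), by damped
#' Newton-Raphson ascent warm-started from the previous grid point.
#' \eqn{\xi_0} is kept positive through a log-reparameterisation.
#'
#' The orders are split into a sympathetic block (Laguerre orders
#' `0..P_symp`) and a parasympathetic block (`P_symp+1..P_parasymp`);
#' the split does not affect the fit, only how [index_series()] reads
#' the coefficients.
#'
#' @param ev An [event_series()].
#' @param W Local observation window (s); default 70.
#' @param step Grid spacing at which the model is revised (s);
#'   default 0.005 (5 ms).
#' @param P_symp,P_parasymp Sympathetic / parasympathetic Laguerre orders;
#'   defaults 2 and 9 (10 bases in total).
#' @param alpha Laguerre decay parameter; default 0.2.
#' @param N_max Laguerre truncation in lags; default 200.
#' @param max_iter Maximum Newton iterations per grid point; default 50.
#' @param grad_tol Gradient sup-norm convergence tolerance; default 1e-6.
#' @param censor Include the right-censoring term \eqn{\log(1 - F)} for
#'   the ongoing interval (default `TRUE`).
#' @param forgetting Exponential forgetting rate (1/s) applied as weights
#'   \eqn{e^{-\rho (t - u_k)}} within the window; 0 (default) gives the
#'   uniform weighting.
#' @param duration Upper end of the evaluation grid (s); defaults to the
#'   last event time.
#' @param engine `"cpp"` (compiled sliding-window solver, default) or
#'   `"r"` (reference implementation in pure R; identical results, used
#'   as the cross-check in the test suite).
#' @return An object of class `pphrv` with components `times` (grid),
#'   `g0`, `g1` (matrix, one column per order), `xi0`, `mu_hp`, `loglik`,
#'   `converged`, `n_beats`, the `basis`, `config`, and the input events.
#' @seealso [index_series()], [ks_time_rescaling()], [simulate.pphrv()]
#' @export
pphrv <- function(ev, W = 70, step = 0.005, P_symp = 2, P_parasymp = 9,
                  alpha = 0.2, N_max = 200, max_iter = 50, grad_tol = 1e-6,
                  censor = TRUE, forgetting = 0, duration = NULL,
                  engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  stopifnot(inherits(ev, "event_series"))
  if (!(W > 0 && step > 0)) stop("W and step must be positive", call. = FALSE)
  if (!(P_symp >= 0 && P_symp < P_parasymp))
    stop("need 0 <= P_symp < P_parasymp", call. = FALSE)
  u <- ev$u
  K <- length(u)
  if (is.null(duration)) duration <- u[K]
  if (duration - u[1] < W)
    stop("recording shorter than the window W", call. = FALSE)
  basis <- laguerre_basis(alpha = alpha, J_max = P_parasymp, N_max = N_max)
  J <- basis$J_max
  kmin <- J + 3L                      # first interval with enough history
  if (K < kmin + 1L)
    stop("too few beats for the Laguerre warm-up", call. = FALSE)

  des <- pp_design_matrix(ev, basis)  # (K+1) x (J+2); row k = [1, l(interval k)]
  hp <- ev$hp

  times <- seq(u[1] + W, duration, by = step)
  p <- J + 2L                         # g0 + g1 block
  fit <- if (engine == "cpp") {
    .pp_fit_cpp(times, u, hp, des, kmin, W, censor, forgetting,
                as.integer(max_iter), grad_tol, numeric(0))
  } else {
    pp_fit_r(times, u, hp, des, kmin, W, censor, forgetting,
             max_iter, grad_tol)
  }
  G <- fit$G
  nb <- as.integer(drop(fit$n_beats))
  conv <- as.logical(drop(fit$converged))
  ll_out <- drop(fit$loglik)
  mu_out <- drop(fit$mu_hp)
  fit$eta <- drop(fit$eta)
  # dof-corrected dispersion: local ML of xi0 is biased upward by about
  # n/(n - p) with p mean parameters (cf. residual variance in lm)
  xi0_out <- exp(fit$eta) * pmax(nb - p, 1L) / pmax(nb, 1L)
  acc_A <- fit$accA
  acc_b <- drop(fit$accb)

  g1 <- G[, -1L, drop = FALSE]
  colnames(g1) <- paste0("g1_", 0:J)
  structure(list(times = times, g0 = G[, 1L], g1 = g1, xi0 = xi0_out,
                 mu_hp = mu_out, loglik = ll_out, converged = conv,
                 n_beats = nb, basis = basis,
                 info = list(A = acc_A, b = acc_b),
                 config = list(W = W, step = step, P_symp = P_symp,
                               P_parasymp = P_parasymp, alpha = alpha,
                               N_max = N_max, max_iter = max_iter,
                               grad_tol = grad_tol, censor = censor,
                               forgetting = forgetting),
                 events = ev),
            class = "pphrv")
}

# Reference R implementation of the sliding-window fit loop; returns the
# same structure as the compiled engine.
pp_fit_r <- function(times, u, hp, des, kmin, W, censor, forgetting,
                     max_iter, grad_tol) {
  nT <- length(times)
  K <- length(u)
  p <- ncol(des)
  G <- matrix(NA_real_, nT, p)
  eta_out <- mu_out <- ll_out <- rep(NA_real_, nT)
  conv <- logical(nT)
  nb <- integer(nT)
  theta <- NULL
  acc_A <- matrix(0, p + 1L, p + 1L)
  acc_b <- numeric(p + 1L)
  k_lo <- kmin; k_hi <- kmin - 1L
  for (it in seq_len(nT)) {
    t <- times[it]
    while (k_hi + 1L <= K && u[k_hi + 1L] <= t) k_hi <- k_hi + 1L
    while (k_lo <= k_hi && u[k_lo - 1L] < t - W) k_lo <- k_lo + 1L
    k_lo <- max(k_lo, kmin)
    ks <- if (k_lo <= k_hi) k_lo:k_hi else integer(0)
    nb[it] <- length(ks)
    if (length(ks) < 2L) next         # not enough local data; non-converged
    X <- des[ks, , drop = FALSE]
    w <- hp[ks]
    wt <- if (forgetting > 0) exp(-forgetting * (t - u[ks])) else rep(1, length(ks))
    kc <- k_hi + 1L
    cens <- censor && kc <= K + 1L && kc >= kmin && t > u[k_hi]
    x_c <- if (cens) des[kc, ] else NULL
    tau <- if (cens) t - u[k_hi] else NA_real_
    if (is.null(theta)) {
      v <- stats::var(w)
      theta <- c(mean(w), rep(0, p - 1L), log(mean(w)^3 / max(v, 1e-8)))
    }
    res <- pp_newton_solve(theta, X, w, wt, x_c, tau,
                           max_iter = max_iter, grad_tol = grad_tol)
    theta <- res$theta
    G[it, ] <- theta[1:p]
    eta_out[it] <- theta[p + 1L]
    ll_out[it] <- res$loglik
    conv[it] <- res$converged
    if (res$converged && !is.null(res$H)) {
      Hn <- -res$H                     # local observed information
      acc_A <- acc_A + Hn
      acc_b <- acc_b + drop(Hn %*% theta)
    }
    mu_out[it] <- sum(des[min(kc, K + 1L), ] * theta[1:p])
  }
  list(G = G, eta = eta_out, loglik = ll_out, mu_hp = mu_out,
       converged = conv, n_beats = nb, accA = acc_A, accb = acc_b)
}

# Design rows: row k holds [1, l_0..l_J] for the interval terminating at u_k.
# History is left-open at the interval start, so the most recent HP entering
# row k is the last completed interval HP_{k-1}, weighted by phi_j(0).
# Row K+1 serves the ongoing interval after the last event.
pp_design_matrix <- function(ev, basis) {
  u <- ev$u
  hp <- ev$hp
  K <- length(u)
  N_max <- basis$N_max
  H <- matrix(0, K + 1L, N_max)
  for (col in seq_len(N_max)) {        # column col holds lag n = col - 1
    k <- seq_len(K + 1L)
    src <- k - col                     # HP_{(k-1) - n}
    ok <- src >= 2L & src <= K
    H[k[ok], col] <- hp[src[ok]]
  }
  cbind(1, H %*% basis$Phi)
}

# log-survival censoring term and its (numeric) gradient in (mu_c, eta)
pp_censor_terms <- function(tau, mu_c, eta, grad = TRUE) {
  f <- function(m, e) {
    if (m <= 0) return(-Inf)
    ig_cdf(tau, m, exp(e), lower.tail = FALSE, log.p = TRUE)
  }
  v <- f(mu_c, eta)
  if (!grad) return(list(value = v))
  hm <- 1e-6 * max(1, abs(mu_c)); he <- 1e-6 * max(1, abs(eta))
  dm <- (f(mu_c + hm, eta) - f(mu_c - hm, eta)) / (2 * hm)
  de <- (f(mu_c, eta + he) - f(mu_c, eta - he)) / (2 * he)
  list(value = v, dmu = dm, deta = de)
}

# local log-likelihood at theta = c(g, eta); returns value only
pp_objective <- function(theta, X, w, wt, x_c, tau) {
  p <- ncol(X)
  g <- theta[1:p]; eta <- theta[p + 1L]; xi0 <- exp(eta)
  mu <- drop(X %*% g)
  if (any(mu <= 0)) return(-Inf)
  ll <- sum(wt * (0.5 * (eta - log(2 * pi) - 3 * log(w)) -
                    0.5 * xi0 * (w - mu)^2 / (mu^2 * w)))
  if (!is.null(x_c)) {
    mu_c <- sum(x_c * g)
    if (mu_c <= 0) return(-Inf)
    ll <- ll + pp_censor_terms(tau, mu_c, eta, grad = FALSE)$value
  }
  ll
}

# gradient and Hessian of the interval part (analytic) plus the censoring
# gradient (numeric, chain-ruled); censoring is omitted from the Hessian --
# backtracking keeps the ascent property and the stationary point is exact.
pp_grad_hess <- function(theta, X, w, wt, x_c, tau) {
  p <- ncol(X)
  g <- theta[1:p]; eta <- theta[p + 1L]; xi0 <- exp(eta)
  mu <- drop(X %*% g)
  if (any(mu <= 0)) return(NULL)
  e <- w - mu
  A <- e^2 / (mu^2 * w)
  dmu  <- wt * xi0 * e / mu^3
  d2mu <- wt * xi0 * (2 * mu - 3 * w) / mu^4
  deta  <- wt * (0.5 - 0.5 * xi0 * A)
  d2eta <- wt * (-0.5 * xi0 * A)
  cross <- dmu                         # d2 ll / dmu deta = xi0 e / mu^3
  grad <- c(drop(crossprod(X, dmu)), sum(deta))
  Hgg <- crossprod(X * d2mu, X)
  Hge <- drop(crossprod(X, cross))
  H <- rbind(cbind(Hgg, Hge), c(Hge, sum(d2eta)))
  if (!is.null(x_c)) {
    mu_c <- sum(x_c * g)
    if (mu_c <= 0) return(NULL)
    ct <- pp_censor_terms(tau, mu_c, eta)
    grad <- grad + c(ct$dmu * x_c, ct$deta)
  }
  list(grad = grad, H = H)
}

# damped Newton ascent with backtracking; returns theta, loglik, converged
# and the interval-part Hessian at the final iterate
pp_newton_solve <- function(theta, X, w, wt, x_c, tau,
                            max_iter = 50, grad_tol = 1e-6) {
  ll <- pp_objective(theta, X, w, wt, x_c, tau)
  if (!is.finite(ll)) {                # recover from an infeasible warm start
    theta <- c(mean(w), rep(0, ncol(X) - 1L),
               log(mean(w)^3 / max(stats::var(w), 1e-8)))
    ll <- pp_objective(theta, X, w, wt, x_c, tau)
  }
  converged <- FALSE
  H_last <- NULL
  for (iter in seq_len(max_iter)) {
    gh <- pp_grad_hess(theta, X, w, wt, x_c, tau)
    if (is.null(gh)) break
    H_last <- gh$H
    if (sqrt(sum(gh$grad^2)) < grad_tol) { converged <- TRUE; break }
    dir <- pp_newton_direction(gh$H, gh$grad)
    if (sqrt(sum(dir^2)) < 1e-7 * (1 + sqrt(sum(theta^2)))) {
      # step below the resolution of the objective: take it outright and
      # let the gradient test decide (any ll change is sub-roundoff)
      cand <- theta + dir
      llc <- pp_objective(cand, X, w, wt, x_c, tau)
      if (is.finite(llc)) { theta <- cand; ll <- max(ll, llc) }
      next
    }
    tstep <- 1
    accepted <- FALSE
    for (bt in 1:40) {
      cand <- theta + tstep * dir
      llc <- pp_objective(cand, X, w, wt, x_c, tau)
      if (is.finite(llc) && llc > ll) {
        gain <- llc - ll
        theta <- cand; ll <- llc; accepted <- TRUE
        if (gain < 1e-13 * (1 + abs(ll))) {
          # ascent exhausted to numerical resolution: one last flag check
          gh <- pp_grad_hess(theta, X, w, wt, x_c, tau)
          if (!is.null(gh)) {
            H_last <- gh$H
            converged <- sqrt(sum(gh$grad^2)) < grad_tol
          }
          accepted <- FALSE            # stop iterating
        }
        break
      }
      tstep <- tstep / 2
    }
    if (!accepted) break
  }
  list(theta = theta, loglik = ll, converged = converged, H = H_last)
}

# Newton ascent direction solve(-H, grad), with ridge escalation and a
# gradient-ascent fallback for indefinite Hessians
pp_newton_direction <- function(H, grad) {
  nH <- -H
  sc <- mean(abs(diag(nH))) + 1e-12
  for (r in c(0, 1e-10, 1e-6, 1e-2) * sc) {
    ch <- tryCatch(chol(nH + diag(r, nrow(nH))), error = function(e) NULL)
    if (!is.null(ch)) return(backsolve(ch, forwardsolve(t(ch), grad)))
  }
  grad / (sc + sqrt(sum(grad^2)))
}

#' History-dependent mean heart period
#'
#' The mean of the inverse-Gaussian waiting-time distribution as a
#' linear combination of Laguerre filter outputs,
#' \deqn{\mu_{HP} = g_0 + \sum_{j=0}^{P_s} g_1(j) l_j +
#'   \sum_{j=P_s+1}^{P_p} g_1(j) l_j,}
#' a single linear combination whose two labelled blocks are read
#' separately by the SAI and PAI combinations.
#'
#' @param g0 Baseline coefficient (s).
#' @param g1 Coefficient vector of length `P_parasymp + 1`.
#' @param l Laguerre output vector of the same length.
#' @param P_symp,P_parasymp Block split orders (defaults 2 and 9); used
#'   only to validate lengths.
#' @return The mean heart period (s).
#' @export
mu_hp <- function(g0, g1, l, P_symp = 2, P_parasymp = 9) {
  if (length(g1) != P_parasymp + 1L || length(l) != P_parasymp + 1L)
    stop("`g1` and `l` must have length P_parasymp + 1", call. = FALSE)
  g0 + sum(g1 * l)
}

#' Local log-likelihood of the point-process model
#'
#' Weighted sum, over intervals fully observed inside \eqn{[t-W, t]}, of
#' the log inverse-Gaussian density of each interval evaluated at its end
#' with \eqn{\mu_{HP}} computed from that interval's own history, plus
#' (optionally) the right-censoring term \eqn{\log(1-F)} for the interval
#' ongoing at `t`.  Exposed mainly for validation; [pphrv()] uses the
#' same computation internally.
#'
#' @inheritParams pphrv
#' @param g0,g1 Baseline coefficient and Laguerre coefficient vector.
#' @param xi0 Inverse-Gaussian shape, > 0.
#' @param t Right edge of the window (s).
#' @param basis A [laguerre_basis()].
#' @return The local log-likelihood value (finite).
#' @export
local_loglik <- function(ev, basis, g0, g1, xi0, t, W = 70,
                         censor = TRUE, forgetting = 0) {
  stopifnot(inherits(ev, "event_series"), xi0 > 0)
  u <- ev$u; K <- length(u)
  kmin <- basis$J_max + 3L
  ks <- intersect(which(u <= t), kmin:K)
  ks <- ks[u[ks - 1L] >= t - W]
  if (length(ks) == 0L) stop("no fully observed intervals in the window",
                             call. = FALSE)
  des <- pp_design_matrix(ev, basis)
  theta <- c(g0, g1, log(xi0))
  k_hi <- max(ks)
  kc <- k_hi + 1L
  cens <- censor && t > u[k_hi] && kc >= kmin
  wt <- if (forgetting > 0) exp(-forgetting * (t - u[ks])) else rep(1, length(ks))
  pp_objective(theta, des[ks, , drop = FALSE], ev$hp[ks], wt,
               if (cens) des[kc, ] else NULL,
               if (cens) t - u[k_hi] else NA_real_)
}

#' One damped Newton-Raphson ascent step of the local likelihood
#'
#' Performs a single backtracking Newton step on \eqn{(g_0, g_1,
#' \log\xi_0)} for the window ending at `t`.  The attained local
#' log-likelihood never decreases across accepted steps; at a stationary
#' point (gradient below `grad_tol`) the parameters are returned
#' unchanged with `converged = TRUE`.
#'
#' @inheritParams local_loglik
#' @param grad_tol Gradient sup-norm tolerance.
#' @return List with updated `g0`, `g1`, `xi0`, `loglik`, `converged`.
#' @export
pp_newton_step <- function(ev, basis, g0, g1, xi0, t, W = 70,
                           censor = TRUE, grad_tol = 1e-6) {
  u <- ev$u; K <- length(u)
  kmin <- basis$J_max + 3L
  ks <- intersect(which(u <= t), kmin:K)
  ks <- ks[u[ks - 1L] >= t - W]
  if (length(ks) == 0L) stop("no fully observed intervals in the window",
                             call. = FALSE)
  des <- pp_design_matrix(ev, basis)
  theta <- c(g0, g1, log(xi0))
  k_hi <- max(ks); kc <- k_hi + 1L
  cens <- censor && t > u[k_hi] && kc >= kmin
  X <- des[ks, , drop = FALSE]; w <- ev$hp[ks]; wt <- rep(1, length(ks))
  x_c <- if (cens) des[kc, ] else NULL
  tau <- if (cens) t - u[k_hi] else NA_real_
  res <- pp_newton_solve(theta, X, w, wt, x_c, tau, max_iter = 1L,
                         grad_tol = grad_tol)
  p <- ncol(X)
  list(g0 = res$theta[1L], g1 = res$theta[2:p], xi0 = exp(res$theta[p + 1L]),
       loglik = res$loglik, converged = res$converged)
}
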