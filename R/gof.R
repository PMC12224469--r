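#' Goodness-of-fit by the time-rescaling theorem
#'
#' Rescales each scored heartbeat interval by the integrated hazard of
#' the fitted time-varying inverse-Gaussian model,
#' \eqn{z_k = \int_{u_{k-1}}^{u_k} \lambda(t)\,dt}; under a correct model
#' the \eqn{z_k} are i.i.d. unit exponentials and
#' \eqn{v_k = 1 - e^{-z_k}} are i.i.d. uniform.  Returns the
#' Kolmogorov-Smirnov distance of the \eqn{v_k} from the uniform CDF
#' together with the 95% acceptance band \eqn{1.36/\sqrt{K}}.
#'
#' Intervals overlapping non-converged grid states are skipped (and
#' counted in `skipped`).  The integrated hazard is computed exactly for
#' piecewise-constant parameters: within each stretch between model
#' revisions the cumulative hazard increment is
#' \eqn{\Lambda(\tau_2) - \Lambda(\tau_1)} with
#' \eqn{\Lambda(\tau) = -\log S(\tau)} of the inverse-Gaussian at the
#' parameters of the most recent revision.
#'
#' @param ev The scored [event_series()] (normally the one the model was
#'   fitted to).
#' @param fit A fitted [pphrv()] model covering the scored intervals.
#' @return List with `ks` (KS statistic), `band_95`, `z` (rescaled
#'   times), `v` (uniforms), `n` (intervals scored), `skipped`.
#' @export
ks_time_rescaling <- function(ev, fit) {
  stopifnot(inherits(ev, "event_series"), inherits(fit, "pphrv"))
  u <- ev$u
  K <- length(u)
  kmin <- fit$basis$J_max + 3L
  t0 <- min(fit$times); t1 <- max(fit$times)
  ks_idx <- which(seq_len(K) >= kmin)
  ks_idx <- ks_idx[u[ks_idx - 1L] >= t0 & u[ks_idx] <= t1]
  if (length(ks_idx) == 0L)
    stop("trajectory does not cover any scored interval", call. = FALSE)
  des <- pp_design_matrix(ev, fit$basis)
  step_grid <- fit$times
  G <- cbind(fit$g0, fit$g1)
  z <- rep(NA_real_, length(ks_idx))
  skipped <- 0L
  for (i in seq_along(ks_idx)) {
    k <- ks_idx[i]
    inside <- step_grid[step_grid > u[k - 1L] & step_grid < u[k]]
    tt <- c(u[k - 1L], inside, u[k])
    gi <- pmax(findInterval(tt[-length(tt)], step_grid), 1L)
    if (!all(fit$converged[gi])) { skipped <- skipped + 1L; next }
    l_row <- des[k, ]
    mu <- drop(G[gi, , drop = FALSE] %*% l_row)
    xi <- fit$xi0[gi]
    tau_lo <- tt[-length(tt)] - u[k - 1L]
    tau_hi <- tt[-1L] - u[k - 1L]
    Lam_hi <- -ig_cdf(tau_hi, mu, xi, lower.tail = FALSE, log.p = TRUE)
    Lam_lo <- ifelse(tau_lo > 0,
                     -ig_cdf(pmax(tau_lo, 1e-12), mu, xi,
                             lower.tail = FALSE, log.p = TRUE), 0)
    z[i] <- sum(Lam_hi - Lam_lo)
  }
  z <- z[!is.na(z)]
  if (length(z) == 0L) stop("all intervals skipped (non-converged states)",
                            call. = FALSE)
  v <- 1 - exp(-z)
  n <- length(v)
  vs <- sort(v)
  D <- max(seq_len(n) / n - vs, vs - (seq_len(n) - 1) / n)
  list(ks = D, band_95 = 1.36 / sqrt(n), z = z, v = v, n = n,
       skipped = skipped)
}
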