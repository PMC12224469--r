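#' @export
print.pphrv <- function(x, ...) {
  cfg <- x$config
  cat("Inverse-Gaussian point-process heart-rate model\n")
  cat(sprintf("  %d events, grid of %d states (step %.3g s, window %g s)\n",
              length(x$events$u), length(x$times), cfg$step, cfg$W))
  cat(sprintf("  Laguerre orders 0..%d (alpha = %g), sympathetic block 0..%d\n",
              cfg$P_parasymp, cfg$alpha, cfg$P_symp))
  cat(sprintf("  converged states: %d / %d\n", sum(x$converged),
              length(x$converged)))
  if (any(x$converged)) {
    cat(sprintf("  mean mu_HP %.3f s, mean xi0 %.1f\n",
                mean(x$mu_hp[x$converged]), mean(x$xi0[x$converged])))
  }
  invisible(x)
}

#' @export
summary.pphrv <- function(object, ...) {
  ok <- object$converged
  est <- c(g0 = mean(object$g0[ok]),
           colMeans(object$g1[ok, , drop = FALSE]),
           xi0 = mean(object$xi0[ok]))
  sds <- c(g0 = stats::sd(object$g0[ok]),
           apply(object$g1[ok, , drop = FALSE], 2, stats::sd),
           xi0 = stats::sd(object$xi0[ok]))
  out <- list(coefficients = cbind(mean = est, sd = sds),
              n_states = length(ok), n_converged = sum(ok),
              mu_hp = c(mean = mean(object$mu_hp[ok]),
                        sd = stats::sd(object$mu_hp[ok])),
              config = object$config)
  class(out) <- "summary.pphrv"
  out
}

#' @export
print.summary.pphrv <- function(x, ...) {
  cat("Point-process heart-rate model: time-averaged local MLEs\n")
  cat(sprintf("  %d / %d converged states; mu_HP %.3f (sd %.3f) s\n\n",
              x$n_converged, x$n_states, x$mu_hp["mean"], x$mu_hp["sd"]))
  print(round(x$coefficients, 5))
  invisible(x)
}

#' Time-averaged parameter estimates
#'
#' Reduces the fitted trajectory to one parameter vector.  The default
#' is the information-weighted time average
#' \eqn{\bar\theta = (\sum_t H_t)^{-1} \sum_t H_t \theta_t}, where
#' \eqn{H_t} is the local observed information at grid time `t`: each
#' state contributes in proportion to how well its window identifies
#' each parameter direction, which pools the overlapping windows into
#' (effectively) the full-recording likelihood solution.  A 70-s window
#' holds too few beats to separate the baseline from the
#' Laguerre-coefficient directions on its own, so the plain arithmetic
#' mean of the local states (`weighted = FALSE`) is noisy along that
#' near-collinear direction and is provided only for inspection.
#'
#' @param object A fitted [pphrv()] model.
#' @param weighted Information-weighted pooling (default `TRUE`).
#' @param ... Unused.
#' @return Named vector: `g0`, `g1_0..g1_J` and `xi0`.
#' @export
coef.pphrv <- function(object, weighted = TRUE, ...) {
  ok <- object$converged
  if (!any(ok)) stop("no converged states", call. = FALSE)
  if (weighted && !is.null(object$info) && any(object$info$A != 0)) {
    th <- tryCatch(solve(object$info$A, object$info$b),
                   error = function(e) NULL)
    if (!is.null(th)) {
      p <- ncol(object$g1) + 1L
      nbar <- mean(object$n_beats[ok])
      out <- c(th[1:p], exp(th[p + 1L]) * max(nbar - p, 1) / nbar)
      names(out) <- c("g0", colnames(object$g1), "xi0")
      return(out)
    }
  }
  c(g0 = mean(object$g0[ok]), colMeans(object$g1[ok, , drop = FALSE]),
    xi0 = mean(object$xi0[ok]))
}

#' Instantaneous mean heart period at requested times
#'
#' @param object A fitted [pphrv()] model.
#' @param times Times (s) at which to evaluate \eqn{\mu_{HP}(t)}; defaults
#'   to the fit grid.
#' @param ... Unused.
#' @return Numeric vector of \eqn{\mu_{HP}} (s); `NA` outside the
#'   converged span.
#' @export
predict.pphrv <- function(object, times = NULL, ...) {
  ok <- object$converged
  if (is.null(times)) {
    out <- object$mu_hp
    out[!ok] <- NA_real_
    return(out)
  }
  stats::approx(object$times[ok], object$mu_hp[ok], xout = times,
                rule = 1)$y
}

#' @export
logLik.pphrv <- function(object, ...) {
  ok <- object$converged
  structure(sum(object$loglik[ok]) / max(1, sum(ok)),
            class = "logLik", df = ncol(object$g1) + 2L, nobs = sum(ok))
}

#' @export
fitted.pphrv <- function(object, ...) predict.pphrv(object)

#' Time-rescaling residuals of the fitted point process
#'
#' @param object A fitted [pphrv()] model.
#' @param type `"uniform"` for the rescaled-interval uniforms
#'   \eqn{1 - e^{-z_k}}, `"exponential"` for the rescaled times
#'   \eqn{z_k}, or `"normal"` for their Gaussian quantiles.
#' @param ... Passed to [ks_time_rescaling()].
#' @return Numeric vector of residuals, one per scored interval.
#' @export
residuals.pphrv <- function(object,
                            type = c("uniform", "exponential", "normal"),
                            ...) {
  type <- match.arg(type)
  ks <- ks_time_rescaling(object$events, object, ...)
  switch(type, uniform = ks$v, exponential = ks$z,
         normal = stats::qnorm(pmin(pmax(ks$v, 1e-12), 1 - 1e-12)))
}

#' @export
plot.pphrv <- function(x, ...) {
  ok <- x$converged
  graphics::plot(x$times[ok], x$mu_hp[ok], type = "l",
                 xlab = "time (s)", ylab = expression(mu[HP] ~ "(s)"),
                 main = "Instantaneous mean heart period", ...)
  u <- x$events$u
  inwin <- u >= min(x$times) & u <= max(x$times)
  graphics::points(u[inwin][-1], diff(x$events$u)[inwin[-1]][seq_len(sum(inwin) - 1)],
                   pch = 16, cex = 0.3, col = "grey50")
  invisible(x)
}

#' Simulate heartbeat series from a fitted model
#'
#' Draws new event series from the fitted model class using the
#' time-averaged converged parameter estimates; a thin wrapper around
#' [simulate_from_model()].
#'
#' @param object A fitted [pphrv()] model.
#' @param nsim Number of series.
#' @param seed Optional RNG seed.
#' @param n_beats Beats per simulated series; defaults to the number of
#'   observed beats.
#' @param ... Unused.
#' @return A list of [event_series()] (length `nsim`), or a single
#'   series if `nsim = 1`.
#' @export
simulate.pphrv <- function(object, nsim = 1, seed = NULL, n_beats = NULL,
                           ...) {
  if (!is.null(seed)) set.seed(seed)
  cf <- coef.pphrv(object)
  p <- ncol(object$g1)
  if (is.null(n_beats)) n_beats <- length(object$events$u)
  out <- lapply(seq_len(nsim), function(i)
    simulate_from_model(g0 = cf[["g0"]], g1 = unname(cf[2:(p + 1L)]),
                        xi0 = cf[["xi0"]], basis = object$basis,
                        n_beats = n_beats))
  if (nsim == 1L) out[[1L]] else out
}
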