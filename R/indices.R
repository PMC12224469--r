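#' Disentangling coefficients for SAI and PAI
#'
#' The sympathetic and parasympathetic activity indices are linear
#' combinations of the fitted Laguerre coefficients,
#' \deqn{SAI = \psi_{S0} + \sum_j \psi_{Sj}\, g_1(j)} over the
#' sympathetic block (orders `0..P_symp`) and analogously for PAI over
#' the parasympathetic block (orders `P_symp+1..P_parasymp`), each then
#' divided by \eqn{\mu_{HP}^2} and floored at zero.
#'
#' The weight values are not identifiable from first principles; the
#' defaults shipped here are synthetic surrogate weights obtained with
#' [calibrate_psi()] on the package's own IPFM simulator (provenance
#' `"synthetic-calibration"`), chosen so that SAI responds to
#' low-frequency (~0.1 Hz) modulation amplitude and PAI to
#' high-frequency (0.14-0.40 Hz) modulation amplitude.  Users with
#' weights from an external source should supply them here.
#'
#' @param psi_S0,psi_P0 Offsets.
#' @param psi_S Weights over the sympathetic block (length `P_symp + 1`).
#' @param psi_P Weights over the parasympathetic block (length
#'   `P_parasymp - P_symp`).
#' @param provenance Free-text source tag.
#' @return An object of class `psi_coefficients`.
#' @export
psi_coefficients <- function(psi_S0, psi_S, psi_P0, psi_P,
                             provenance = "user") {
  structure(list(psi_S0 = psi_S0, psi_S = as.numeric(psi_S),
                 psi_P0 = psi_P0, psi_P = as.numeric(psi_P),
                 provenance = provenance),
            class = "psi_coefficients")
}

#' @rdname psi_coefficients
#' @export
psi_default <- function() {
  # frozen output of calibrate_psi(duration = 420, seeds = 1:3,
  # step = 0.25) on the IPFM simulator (see the methods vignette for the
  # procedure); arbitrary units
  psi_coefficients(
    psi_S0 = 0.5,
    psi_S = c(0.4980, 0.8629, -0.0863),
    psi_P0 = 0.5,
    psi_P = c(0.1968, -0.0735, -0.5445, -0.0739, 0.6131, 0.3008, 0.4330),
    provenance = "synthetic-calibration")
}

#' Read / write psi coefficients as JSON
#'
#' Schema: object with numeric scalar `psi_S0`, array `psi_S`, scalar
#' `psi_P0`, array `psi_P`, string `provenance`.
#'
#' @param path File path.
#' @param psi A [psi_coefficients()] object.
#' @return `read_psi` returns a [psi_coefficients()] object.
#' @export
read_psi <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  psi_coefficients(x$psi_S0, x$psi_S, x$psi_P0, x$psi_P,
                   provenance = x$provenance %||% "file")
}

#' @rdname read_psi
#' @export
write_psi <- function(psi, path) {
  jsonlite::write_json(unclass(psi), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Normalize a raw index value by the squared mean heart period
#'
#' @param raw Raw index value (a.u.).
#' @param mu_hp Mean heart period (s), > 0.
#' @return `raw / mu_hp^2`.
#' @export
normalize_index <- function(raw, mu_hp) {
  if (any(mu_hp <= 0)) stop("`mu_hp` must be positive", call. = FALSE)
  raw / mu_hp^2
}

# shared kernel: linear combination over a g1 block, normalized, floored
index_from_block <- function(g1_block, psi0, psi_w, mu_hp) {
  if (length(psi_w) != ncol(g1_block))
    stop("psi weight length does not match the coefficient block",
         call. = FALSE)
  raw <- psi0 + drop(g1_block %*% psi_w)
  pmax(normalize_index(raw, mu_hp), 0)
}

#' Instantaneous sympathetic / parasympathetic index at one state
#'
#' @param g1 Full Laguerre coefficient vector (orders `0..P_parasymp`).
#' @param mu_hp Mean heart period at the state (s), > 0.
#' @param psi A [psi_coefficients()] object.
#' @param P_symp Sympathetic order; default 2.
#' @param converged State convergence flag; a non-converged state yields
#'   `NA` rather than a fabricated value.
#' @return Index value (a.u., >= 0), or `NA`.
#' @export
compute_sai <- function(g1, mu_hp, psi = psi_default(), P_symp = 2,
                        converged = TRUE) {
  if (!isTRUE(converged)) return(NA_real_)
  index_from_block(matrix(g1[1:(P_symp + 1L)], 1), psi$psi_S0, psi$psi_S,
                   mu_hp)
}

#' @rdname compute_sai
#' @export
compute_pai <- function(g1, mu_hp, psi = psi_default(), P_symp = 2,
                        converged = TRUE) {
  if (!isTRUE(converged)) return(NA_real_)
  index_from_block(matrix(g1[-(1:(P_symp + 1L))], 1), psi$psi_P0,
                   psi$psi_P, mu_hp)
}

#' Instantaneous SAI / PAI series from a fitted model
#'
#' Applies the disentangling combination, the \eqn{1/\mu_{HP}^2}
#' normalization and the zero floor at every grid state of a fitted
#' [pphrv()] trajectory.  Non-converged states become missing values and
#' are excluded from downstream resampling.
#'
#' @param fit A fitted [pphrv()] model.
#' @param psi A [psi_coefficients()] object; default [psi_default()].
#' @return An object of class `instantaneous_series`: data frame with
#'   columns `time`, `sai`, `pai`, `mu_hp`, `converged`, plus attributes
#'   `step` and `psi`.
#' @export
index_series <- function(fit, psi = psi_default()) {
  stopifnot(inherits(fit, "pphrv"))
  ok <- fit$converged
  if (!any(ok)) stop("no converged states in the trajectory", call. = FALSE)
  P_symp <- fit$config$P_symp
  sym <- fit$g1[, 1:(P_symp + 1L), drop = FALSE]
  par <- fit$g1[, -(1:(P_symp + 1L)), drop = FALSE]
  sai <- pai <- rep(NA_real_, length(fit$times))
  mu <- fit$mu_hp
  sai[ok] <- index_from_block(sym[ok, , drop = FALSE], psi$psi_S0,
                              psi$psi_S, mu[ok])
  pai[ok] <- index_from_block(par[ok, , drop = FALSE], psi$psi_P0,
                              psi$psi_P, mu[ok])
  out <- data.frame(time = fit$times, sai = sai, pai = pai, mu_hp = mu,
                    converged = ok)
  attr(out, "step") <- fit$config$step
  attr(out, "psi") <- psi
  class(out) <- c("instantaneous_series", "data.frame")
  out
}

#' Calibrate surrogate psi weights on the IPFM simulator
#'
#' Fits the point-process model to IPFM recordings at baseline, with the
#' LF amplitude doubled, and with the HF amplitude halved, and builds
#' disentangling weights from the displacement of the time-averaged
#' Laguerre coefficients: within the sympathetic block, the LF-doubling
#' displacement is orthogonalized against the HF-halving displacement
#' (so SAI responds to LF drive but is first-order insensitive to vagal
#' change), and symmetrically for the parasympathetic block, signed so
#' that PAI falls under vagal withdrawal.  Weights are scaled to unit
#' norm; offsets default to 0.5 a.u. so baseline indices sit away from
#' the zero floor.
#'
#' @param duration Recording length per condition (s).
#' @param seeds Seeds averaged over.
#' @param step Fit grid spacing (s); calibration does not require the
#'   5 ms production grid.
#' @param ... Passed to [pphrv()].
#' @return A [psi_coefficients()] object with provenance
#'   `"synthetic-calibration"`.
#' @export
calibrate_psi <- function(duration = 420, seeds = 1:3, step = 0.25, ...) {
  conds <- list(base = c(1, 1), lf2 = c(2, 1), hf05 = c(1, 0.5))
  means <- lapply(conds, function(sc) {
    g <- lapply(seeds, function(s) {
      set.seed(s)
      ev <- simulate_ipfm(duration, epochs = data.frame(
        start = 0, end = duration, lf_scale = sc[1], hf_scale = sc[2]),
        jitter_sd = 0.005)
      fit <- pphrv(ev, step = step, ...)
      colMeans(fit$g1[fit$converged, , drop = FALSE])
    })
    Reduce(`+`, g) / length(g)
  })
  P_symp <- list(...)$P_symp %||% 2
  sym_idx <- 1:(P_symp + 1L)
  d_lf <- means$lf2 - means$base        # response to sympathetic-like drive
  d_hf <- means$hf05 - means$base       # response to vagal withdrawal
  ortho <- function(a, b) a - sum(a * b) / sum(b * b) * b
  wS <- ortho(d_lf[sym_idx], d_hf[sym_idx])
  wP <- -ortho(d_hf[-sym_idx], d_lf[-sym_idx])  # PAI drops when HF drops
  psi_coefficients(psi_S0 = 0.5, psi_S = wS / sqrt(sum(wS^2)),
                   psi_P0 = 0.5, psi_P = wP / sqrt(sum(wP^2)),
                   provenance = "synthetic-calibration")
}

#' Write an instantaneous index series as CSV
#'
#' @param x An [index_series()] result.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_indices <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_indices
#' @param step Grid spacing override if the file lacks uniform spacing
#'   metadata (inferred from the time column by default).
#' @export
read_indices <- function(path, step = NULL) {
  df <- utils::read.csv(path)
  if (is.null(step)) step <- stats::median(diff(df$time))
  attr(df, "step") <- step
  class(df) <- c("instantaneous_series", "data.frame")
  df
}
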