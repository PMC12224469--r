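#' Regressor series on the fMRI volume grid
#'
#' Thin container for one value per fMRI volume.
#'
#' @param values One value per volume (`NA` for missing volumes).
#' @param tr Repetition time (s); study default 0.72.
#' @param n_vols Number of volumes; study default 1200.
#' @param convolved,standardized State flags.
#' @return An object of class `regressor_series`.
#' @export
regressor_series <- function(values, tr = 0.72, n_vols = length(values),
                             convolved = FALSE, standardized = FALSE) {
  values <- as.numeric(values)
  if (length(values) != n_vols)
    stop("`values` must have length `n_vols`", call. = FALSE)
  structure(list(values = values, tr = tr, n_vols = as.integer(n_vols),
                 convolved = convolved, standardized = standardized),
            class = "regressor_series")
}

#' @export
print.regressor_series <- function(x, ...) {
  cat(sprintf("fMRI regressor: %d volumes at TR %.3g s%s%s, %d missing\n",
              x$n_vols, x$tr,
              if (x$convolved) ", HRF-convolved" else "",
              if (x$standardized) ", standardized" else "",
              sum(is.na(x$values))))
  invisible(x)
}

#' Resample an instantaneous index series at fMRI volume times
#'
#' Synchronizes an index series with the fMRI acquisition: the value at
#' volume `v` is the series value at `t = offset + v * tr` (v = 0-based),
#' linearly interpolated between the two bracketing fine-grid points
#' (nearest-neighbour available via `method`).  Missing (non-converged)
#' stretches shorter than `max_gap` seconds are bridged linearly; volumes
#' inside longer gaps stay missing and are later dropped from the GLM.
#'
#' @param series An [index_series()] data frame.
#' @param column Which column to resample (`"sai"`, `"pai"` or
#'   `"mu_hp"`).
#' @param tr Repetition time (s); default 0.72.
#' @param n_vols Number of volumes; default 1200.
#' @param offset Time of volume 0 in the series clock (s); default the
#'   first converged sample (the fit grid starts one window length into
#'   the recording).
#' @param max_gap Longest missing gap (s) bridged by interpolation;
#'   default 2.
#' @param method `"linear"` (default) or `"nearest"`.
#' @return A [regressor_series()].
#' @export
resample_at_volumes <- function(series, column = "sai", tr = 0.72,
                                n_vols = 1200, offset = NULL,
                                max_gap = 2, method = c("linear", "nearest")) {
  method <- match.arg(method)
  stopifnot(column %in% names(series))
  tt <- series$time
  v <- series[[column]]
  ok <- !is.na(v)
  if (!any(ok)) stop("series has no observed values", call. = FALSE)
  if (is.null(offset)) offset <- tt[which(ok)[1L]]
  vol_t <- offset + (seq_len(n_vols) - 1L) * tr
  if (vol_t[1] < tt[which(ok)[1L]] - 1e-9 ||
      vol_t[n_vols] > tt[max(which(ok))] + 1e-9)
    stop(sprintf(
      "series covers [%.2f, %.2f] s but volumes span [%.2f, %.2f] s",
      tt[which(ok)[1L]], tt[max(which(ok))], vol_t[1], vol_t[n_vols]),
      call. = FALSE)
  if (method == "linear") {
    out <- stats::approx(tt[ok], v[ok], xout = vol_t, rule = 2)$y
  } else {
    out <- v[ok][vapply(vol_t, function(z) which.min(abs(tt[ok] - z)), 1L)]
  }
  # re-blank volumes inside long missing gaps
  if (any(!ok)) {
    gaps <- rle(ok)
    ends <- cumsum(gaps$lengths)
    starts <- ends - gaps$lengths + 1L
    for (g in which(!gaps$values)) {
      g0 <- tt[max(1L, starts[g] - 1L)]
      g1 <- tt[min(length(tt), ends[g] + 1L)]
      if (g1 - g0 >= max_gap) out[vol_t > g0 & vol_t < g1] <- NA_real_
    }
  }
  regressor_series(out, tr = tr, n_vols = n_vols)
}

#' Canonical double-gamma hemodynamic response kernel
#'
#' Difference of two gamma densities: a positive response peaking around
#' `peak_delay` seconds and a late undershoot around `undershoot_delay`
#' seconds scaled by `ratio`, normalized to unit peak.
#'
#' @param dt Sampling interval of the kernel (s).
#' @param peak_delay,undershoot_delay Delays (s); defaults 6 and 16.
#' @param peak_disp,undershoot_disp Dispersions (s); defaults 1.
#' @param ratio Undershoot amplitude ratio; default 1/6.
#' @param duration Kernel support (s); default 32.
#' @return An object of class `hrf_kernel`: list with `dt`, `t`,
#'   `weights` (peak-normalized), `params`.
#' @export
double_gamma_hrf <- function(dt, peak_delay = 6, undershoot_delay = 16,
                             peak_disp = 1, undershoot_disp = 1,
                             ratio = 1 / 6, duration = 32) {
  if (dt <= 0 || peak_delay <= 0 || undershoot_delay <= 0 ||
      peak_disp <= 0 || undershoot_disp <= 0 || duration <= 0)
    stop("all HRF parameters must be positive", call. = FALSE)
  tt <- seq(0, duration, by = dt)
  # shape = delay/dispersion + 1 puts the gamma mode exactly at the delay
  h <- stats::dgamma(tt, shape = peak_delay / peak_disp + 1,
                     scale = peak_disp) -
    ratio * stats::dgamma(tt, shape = undershoot_delay / undershoot_disp + 1,
                          scale = undershoot_disp)
  h <- h / max(h)
  structure(list(dt = dt, t = tt, weights = h,
                 params = list(peak_delay = peak_delay,
                               undershoot_delay = undershoot_delay,
                               peak_disp = peak_disp,
                               undershoot_disp = undershoot_disp,
                               ratio = ratio, duration = duration)),
            class = "hrf_kernel")
}

#' Convolve a volume-grid regressor with an HRF kernel
#'
#' Causal discrete convolution truncated to the volume count.  The
#' kernel is resampled to the TR internally if sampled at a different
#' interval.  Missing volumes are bridged for the convolution and
#' re-blanked afterwards, so missingness does not spread over the kernel
#' support.  By default the result is standardized (demeaned, unit
#' variance) so first-level effect sizes are comparable across subjects.
#'
#' @param reg A [regressor_series()].
#' @param hrf An [double_gamma_hrf()] kernel; default built at the
#'   regressor's TR.
#' @param standardize Demean and scale to unit variance (default `TRUE`).
#' @return A convolved [regressor_series()].
#' @export
convolve_regressor <- function(reg, hrf = NULL, standardize = TRUE) {
  stopifnot(inherits(reg, "regressor_series"))
  v <- reg$values
  if (all(is.na(v))) stop("regressor is entirely missing", call. = FALSE)
  if (is.null(hrf)) hrf <- double_gamma_hrf(dt = reg$tr)
  w <- hrf$weights
  if (abs(hrf$dt - reg$tr) > 1e-9) {
    tt <- seq(0, max(hrf$t), by = reg$tr)
    w <- stats::approx(hrf$t, hrf$weights, xout = tt, rule = 2)$y
  }
  nas <- is.na(v)
  if (any(nas)) {
    idx <- which(!nas)
    v <- stats::approx(idx, v[idx], xout = seq_along(v), rule = 2)$y
  }
  out <- stats::convolve(v, rev(w), type = "open")[seq_len(reg$n_vols)]
  out[nas] <- NA_real_
  if (standardize) {
    out <- (out - mean(out, na.rm = TRUE)) / stats::sd(out, na.rm = TRUE)
  }
  regressor_series(out, tr = reg$tr, n_vols = reg$n_vols,
                   convolved = TRUE, standardized = standardize)
}

#' Write / read a volume-grid regressor as CSV
#'
#' Columns: `volume` (0-based), `time` (s), `value`.
#'
#' @param reg A [regressor_series()].
#' @param path File path.
#' @export
write_regressor <- function(reg, path) {
  utils::write.csv(data.frame(volume = seq_len(reg$n_vols) - 1L,
                              time = (seq_len(reg$n_vols) - 1L) * reg$tr,
                              value = reg$values),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_regressor
#' @param tr,convolved,standardized Metadata not stored in the CSV.
#' @export
read_regressor <- function(path, tr = 0.72, convolved = TRUE,
                           standardized = TRUE) {
  df <- utils::read.csv(path)
  regressor_series(df$value, tr = tr, convolved = convolved,
                   standardized = standardized)
}
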