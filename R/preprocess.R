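#' Detect heartbeat events in a pulse waveform
#'
#' Prominence-style local-maximum search on a photoplethysmogram (PPG) or
#' similar pulse signal: peaks must exceed an amplitude threshold and be
#' separated by a refractory period of `60/max_rate` seconds.  Peak times
#' are optionally refined to sub-sample precision by parabolic
#' interpolation through the three samples around each maximum.
#'
#' @param x Numeric vector of waveform samples on a uniform grid.
#' @param fs Sampling rate (Hz); pulse-oximetry default 400.
#' @param min_rate,max_rate Physiological heart-rate bounds (beats/min);
#'   must satisfy 20 <= min_rate < max_rate <= 220.
#' @param min_height Peak amplitude threshold.  `NULL` (default) sets it
#'   adaptively to the signal median plus half the median-to-95th-percentile
#'   excursion; the detection threshold is deliberately exposed because no
#'   universal value exists for unscaled pulse signals.
#' @param refine Parabolic sub-sample refinement of peak times
#'   (default `TRUE`).
#' @return An [event_series()] of detected beat times (s, in the
#'   waveform's own clock, 0 at the first sample).
#' @export
detect_beats <- function(x, fs = 400, min_rate = 40, max_rate = 180,
                         min_height = NULL, refine = TRUE) {
  if (fs <= 0) stop("`fs` must be positive", call. = FALSE)
  if (!(min_rate >= 20 && min_rate < max_rate && max_rate <= 220))
    stop("need 20 <= min_rate < max_rate <= 220", call. = FALSE)
  x <- as.numeric(x)
  if (any(!is.finite(x))) stop("waveform must be finite", call. = FALSE)
  if (length(x) < 2 * fs)
    stop("waveform too short: need at least 2 s of signal", call. = FALSE)
  if (is.null(min_height)) {
    med <- stats::median(x)
    min_height <- med + 0.5 * (stats::quantile(x, 0.95, names = FALSE) - med)
  }
  refractory <- ceiling(60 / max_rate * fs)
  pk <- pracma::findpeaks(x, minpeakheight = min_height,
                          minpeakdistance = refractory)
  if (is.null(pk) || nrow(pk) == 0L)
    stop("no pulse peaks detected (flat or sub-threshold signal)",
         call. = FALSE)
  idx <- sort(pk[, 2])
  t_pk <- (idx - 1) / fs
  if (refine) {
    ok <- idx > 1L & idx < length(x)
    i <- idx[ok]
    denom <- x[i - 1L] - 2 * x[i] + x[i + 1L]
    shift <- ifelse(abs(denom) > .Machine$double.eps,
                    0.5 * (x[i - 1L] - x[i + 1L]) / denom, 0)
    shift <- pmax(pmin(shift, 0.5), -0.5)
    t_pk[ok] <- t_pk[ok] + shift / fs
  }
  if (length(t_pk) < 2L)
    stop("fewer than two beats detected", call. = FALSE)
  event_series(t_pk)
}

# local median HP around beat k over `window` surrounding beats (self excluded)
local_median_hp <- function(hp, k, window = 10L) {
  half <- window %/% 2L
  idx <- max(2L, k - half):min(length(hp), k + half)
  idx <- setdiff(idx, k)
  stats::median(hp[idx], na.rm = TRUE)
}

#' Correct physiological and algorithmic artifacts in a beat series
#'
#' Rule-based correction against a local median heart period (window of 10
#' surrounding beats): a spurious extra detection splits one true interval
#' into two short ones whose sum matches the local median, and is merged;
#' a missed beat produces an interval near a multiple of the local median,
#' and is split by inserting evenly spaced interpolated events.  The
#' procedure is deterministic and idempotent.
#'
#' @param ev An [event_series()] with at least 11 beats.
#' @param tol Relative deviation tolerance in (0, 1); default 0.3.  An HP
#'   pair with both members below `(1 - tol)` of the local median (and sum
#'   within `tol` of it) is merged; an HP above `(2 - tol)` of the local
#'   median is split.
#' @param max_passes Safety cap on correction sweeps.
#' @return A corrected [event_series()]; `flags` mark merged beats as
#'   `"corrected"` and inserted beats as `"interpolated"`.
#' @export
correct_artifacts <- function(ev, tol = 0.3, max_passes = 10L) {
  stopifnot(inherits(ev, "event_series"))
  if (!(tol > 0 && tol < 1)) stop("`tol` must be in (0, 1)", call. = FALSE)
  if (length(ev$u) < 11L)
    stop("need at least 11 beats for local-median correction", call. = FALSE)
  u <- ev$u
  flags <- ev$flags
  for (pass in seq_len(max_passes)) {
    hp <- c(NA_real_, diff(u))
    K <- length(u)
    changed <- FALSE
    # merge spurious beats: scan for u_k whose flanking HPs are both short
    k <- 2L
    keep <- rep(TRUE, K)
    while (k <= K - 1L) {
      m <- local_median_hp(hp, k)
      if (!is.na(hp[k]) && !is.na(hp[k + 1L]) &&
          hp[k] < (1 - tol) * m && hp[k + 1L] < (1 - tol) * m &&
          abs(hp[k] + hp[k + 1L] - m) < tol * m) {
        keep[k] <- FALSE
        flags[k + 1L] <- "corrected"
        changed <- TRUE
        k <- k + 2L
      } else k <- k + 1L
    }
    if (changed) {
      u <- u[keep]; flags <- flags[keep]
      next
    }
    # split long intervals from missed beats
    hp <- c(NA_real_, diff(u))
    K <- length(u)
    new_u <- list(); new_f <- list()
    for (k in seq_len(K)) {
      new_u[[length(new_u) + 1L]] <- u[k]
      new_f[[length(new_f) + 1L]] <- flags[k]
      if (k < K) {
        gap <- u[k + 1L] - u[k]
        m <- local_median_hp(hp, k + 1L)
        if (gap > (2 - tol) * m) {
          n_ins <- max(1L, round(gap / m) - 1L)
          ts <- u[k] + gap * seq_len(n_ins) / (n_ins + 1L)
          new_u[[length(new_u) + 1L]] <- ts
          new_f[[length(new_f) + 1L]] <- rep("interpolated", n_ins)
          changed <- TRUE
        }
      }
    }
    if (!changed) break
    u <- unlist(new_u); flags <- unlist(new_f)
  }
  event_series(u, flags = flags)
}

#' Read a single-column pulse waveform from CSV/TSV
#'
#' @param path File path; one sample per row, optional header.
#' @return Numeric vector of samples.
#' @export
read_waveform <- function(path) {
  first <- trimws(readLines(path, n = 1L))
  sep <- if (grepl(",", first)) "," else if (grepl("\t", first)) "\t" else ""
  has_header <- is.na(suppressWarnings(
    as.numeric(strsplit(first, "[,\t ]+")[[1]][1])))
  df <- utils::read.table(path, header = has_header, sep = sep)
  as.numeric(df[[1L]])
}
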