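#' Heartbeat event series
#'
#' Container for an ordered set of heartbeat event times \eqn{u_k}
#' (k = 1..K) and the derived heart periods
#' \eqn{HP_k = u_k - u_{k-1} > 0}.  The heart period attaches to the
#' terminating event, so the first event carries no HP.
#'
#' @param u Strictly increasing event times (s).
#' @param flags Optional per-beat quality tags, one of `"original"`,
#'   `"corrected"`, `"interpolated"`.  Defaults to all `"original"`.
#' @return An object of class `event_series`: list with `u` (times),
#'   `hp` (length K, `hp[1]` is `NA`), `flags`.
#' @export
#' @examples
#' ev <- event_series(c(0, 0.8, 1.7))
#' ev$hp   # NA 0.8 0.9
event_series <- function(u, flags = NULL) {
  u <- as.numeric(u)
  if (length(u) < 2L) stop("need at least two events", call. = FALSE)
  if (any(!is.finite(u))) stop("event times must be finite", call. = FALSE)
  if (any(diff(u) <= 0))
    stop("event times must be strictly increasing", call. = FALSE)
  if (is.null(flags)) flags <- rep("original", length(u))
  flags <- match.arg(flags, c("original", "corrected", "interpolated"),
                     several.ok = TRUE)
  if (length(flags) != length(u))
    stop("`flags` must match the number of events", call. = FALSE)
  structure(list(u = u, hp = c(NA_real_, diff(u)), flags = flags),
            class = "event_series")
}

#' @export
print.event_series <- function(x, ...) {
  K <- length(x$u)
  cat(sprintf("Heartbeat event series: %d events over %.1f s\n",
              K, x$u[K] - x$u[1]))
  cat(sprintf("  mean HP %.3f s (%.1f bpm), range [%.3f, %.3f] s\n",
              mean(x$hp, na.rm = TRUE), 60 / mean(x$hp, na.rm = TRUE),
              min(x$hp, na.rm = TRUE), max(x$hp, na.rm = TRUE)))
  n_mod <- sum(x$flags != "original")
  if (n_mod > 0) cat(sprintf("  %d beat(s) corrected or interpolated\n", n_mod))
  invisible(x)
}

#' Heart periods from event times
#'
#' @param u Strictly increasing event times (s), length >= 2.
#' @return An [event_series()] with `hp[k] = u[k] - u[k-1]`.
#' @export
compute_hp <- function(u) event_series(u)

#' Read / write heartbeat events as CSV
#'
#' The on-disk format is a CSV with columns `k`, `u`, `hp`, `flag`.
#' A single-column file of times is also accepted on read.
#'
#' @param path File path.
#' @param ev An [event_series()].
#' @return `read_events` returns an [event_series()];
#'   `write_events` returns `path` invisibly.
#' @export
read_events <- function(path) {
  df <- utils::read.csv(path)
  if (ncol(df) == 1L) return(event_series(df[[1L]]))
  if (!all(c("u", "flag") %in% names(df)))
    stop("expected columns `u` and `flag` (or a single column of times)",
         call. = FALSE)
  event_series(df$u, flags = df$flag)
}

#' @rdname read_events
#' @export
write_events <- function(ev, path) {
  stopifnot(inherits(ev, "event_series"))
  utils::write.csv(
    data.frame(k = seq_along(ev$u), u = ev$u, hp = ev$hp, flag = ev$flags),
    path, row.names = FALSE)
  invisible(path)
}
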