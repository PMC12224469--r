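#' Integral pulse frequency modulation (IPFM) heartbeat generator
#'
#' Generates heartbeat events from a modulated integrate-and-fire
#' mechanism: an event fires every time \eqn{\int (1 + m(t))/T_0\,dt}
#' accumulates one unit, with modulation
#' \eqn{m(t) = a_{LF}\sin(2\pi f_{LF} t) + a_{HF}\sin(2\pi f_{HF} t)}
#' optionally rescaled inside epochs.  The low-frequency (~0.1 Hz)
#' component emulates sympathetically/baroreflex-driven variability, the
#' high-frequency (0.14-0.40 Hz) component vagally driven variability.
#' IPFM is deliberately a different model class from the inverse-Gaussian
#' point process, so parameter-recovery tests on IPFM data are not
#' circular.
#'
#' @param duration Recording length (s); must exceed `10 * mean_hp`.
#' @param mean_hp Baseline heart period \eqn{T_0} (s); default 0.9.
#' @param lf,hf Length-2 vectors `c(freq_hz, amplitude)`; defaults
#'   `c(0.1, 0.1)` and `c(0.25, 0.1)`.  The LF frequency must be below
#'   0.14 Hz and the HF frequency inside [0.14, 0.40] Hz.
#' @param epochs Optional data frame / matrix with columns `start`, `end`
#'   (s), `lf_scale`, `hf_scale` applied multiplicatively inside each
#'   epoch.
#' @param dc Constant modulation offset added to `m(t)` (default 0); a
#'   positive value raises the mean rate uniformly.
#' @param jitter_sd Standard deviation of white interval jitter (s) added
#'   to each fired interval (default 0, i.e. the pure deterministic
#'   integrate-and-fire mechanism), representing beat-timing noise.
#' @param dt Integration step (s) for the rate integral.
#' @return An [event_series()] with attribute `"truth"` holding the
#'   modulation function settings.
#' @export
simulate_ipfm <- function(duration, mean_hp = 0.9, lf = c(0.1, 0.1),
                          hf = c(0.25, 0.1), epochs = NULL, dc = 0,
                          jitter_sd = 0, dt = 0.001) {
  if (duration <= 10 * mean_hp)
    stop("duration must exceed 10 * mean_hp", call. = FALSE)
  if (lf[2] < 0 || hf[2] < 0) stop("amplitudes must be >= 0", call. = FALSE)
  if (lf[1] >= 0.14) stop("LF frequency must be below 0.14 Hz", call. = FALSE)
  if (hf[1] < 0.14 || hf[1] > 0.40)
    stop("HF frequency must lie in [0.14, 0.40] Hz", call. = FALSE)
  tt <- seq(0, duration, by = dt)
  lf_a <- rep(lf[2], length(tt))
  hf_a <- rep(hf[2], length(tt))
  if (!is.null(epochs)) {
    epochs <- as.data.frame(epochs)
    for (r in seq_len(nrow(epochs))) {
      in_ep <- tt >= epochs$start[r] & tt < epochs$end[r]
      lf_a[in_ep] <- lf_a[in_ep] * epochs$lf_scale[r]
      hf_a[in_ep] <- hf_a[in_ep] * epochs$hf_scale[r]
    }
  }
  m <- dc + lf_a * sin(2 * pi * lf[1] * tt) + hf_a * sin(2 * pi * hf[1] * tt)
  if (any(abs(m) >= 1))
    stop("modulation |m(t)| >= 1: instantaneous rate would be non-positive",
         call. = FALSE)
  # acc[i] = integral of the modulated rate from 0 to tt[i]
  acc <- cumsum(c(0, (1 + m[-length(m)]) / mean_hp * dt))
  cross <- which(diff(floor(acc)) >= 1L)
  # linear interpolation of the integer crossing inside each step
  frac <- (floor(acc[cross + 1L]) - acc[cross]) /
    (acc[cross + 1L] - acc[cross])
  u <- tt[cross] + frac * dt
  if (jitter_sd > 0) {
    iv <- diff(c(0, u))
    iv <- pmax(iv + stats::rnorm(length(iv), 0, jitter_sd), 0.2 * mean_hp)
    u <- cumsum(iv)
  }
  ev <- event_series(u)
  attr(ev, "truth") <- list(mean_hp = mean_hp, lf = lf, hf = hf,
                            epochs = epochs, jitter_sd = jitter_sd)
  ev
}

#' Simulate heartbeats from the inverse-Gaussian point-process model
#'
#' Draws each next heart period from the inverse-Gaussian distribution
#' whose mean is the Laguerre expansion of the simulated past, i.e. from
#' the model class fitted by [pphrv()].  Used as the within-class oracle
#' for parameter recovery and goodness-of-fit tests.
#'
#' @param g0 Baseline coefficient (s).
#' @param g1 Laguerre coefficient vector, length `J_max + 1`.
#' @param xi0 Inverse-Gaussian shape (s), > 0.
#' @param basis A [laguerre_basis()].
#' @param n_beats Number of beats to simulate.
#' @return An [event_series()] of `n_beats` events starting at 0, with
#'   attribute `"truth"` echoing the parameters.  The series is
#'   self-starting: the first interval has an empty history
#'   (\eqn{\mu = g_0}) and the Laguerre filter grows with the available
#'   past, exactly as the fitting side evaluates it, so every simulated
#'   interval follows the scored model.
#' @export
simulate_from_model <- function(g0, g1, xi0, basis = laguerre_basis(),
                                n_beats) {
  J <- basis$J_max
  if (length(g1) != J + 1L) stop("`g1` must have length J_max + 1",
                                 call. = FALSE)
  if (xi0 <= 0) stop("`xi0` must be positive", call. = FALSE)
  if (n_beats < J + 4L) stop("`n_beats` too small", call. = FALSE)
  S <- colSums(basis$Phi)
  denom <- 1 - sum(g1 * S)
  if (denom <= 0 || g0 / denom <= 0)
    stop("parameters admit no positive stationary mean heart period",
         call. = FALSE)
  hp <- rep(NA_real_, n_beats)
  Phi <- basis$Phi
  for (k in 2:n_beats) {
    n_lags <- min(k - 2L, basis$N_max)   # lags 0..n_lags-1, newest HP first
    l <- if (n_lags > 0L)
      drop(crossprod(Phi[seq_len(n_lags), , drop = FALSE],
                     hp[k - seq_len(n_lags)])) else rep(0, J + 1L)
    mu <- g0 + sum(g1 * l)
    if (!is.finite(mu) || mu <= 0)
      stop(sprintf("mu_HP <= 0 at simulated beat %d", k), call. = FALSE)
    hp[k] <- ig_sample(1L, mu, xi0)
  }
  ev <- event_series(cumsum(c(0, hp[-1L])))
  attr(ev, "truth") <- list(g0 = g0, g1 = g1, xi0 = xi0,
                            stationary_mu = g0 / denom)
  ev
}

#' Synthesize a pulse waveform from heartbeat events
#'
#' Superposes a stereotyped Gaussian-shaped pulse template centred at
#' each event over a uniform sampling grid, plus white noise: a
#' round-trip fixture for [detect_beats()].
#'
#' @param ev An [event_series()].
#' @param fs Sampling rate (Hz), >= 50; default 400.
#' @param pulse_width Template standard deviation (s); default 0.05.
#'   Must stay below the smallest heart period.
#' @param amplitude Pulse peak amplitude; default 1.
#' @param noise_sd White-noise standard deviation; default 0.
#' @return Numeric vector of samples spanning `[0, max(u) + 1]` s, with
#'   attribute `"fs"`.
#' @export
synth_ppg <- function(ev, fs = 400, pulse_width = 0.05, amplitude = 1,
                      noise_sd = 0) {
  stopifnot(inherits(ev, "event_series"))
  if (fs < 50) stop("`fs` must be at least 50 Hz", call. = FALSE)
  if (pulse_width * 4 > min(ev$hp, na.rm = TRUE))
    stop("pulse templates would overlap: reduce `pulse_width`",
         call. = FALSE)
  t_end <- max(ev$u) + 1
  tt <- seq(0, t_end, by = 1 / fs)
  x <- numeric(length(tt))
  half <- 4 * pulse_width
  for (uk in ev$u) {
    i <- which(tt >= uk - half & tt <= uk + half)
    x[i] <- x[i] + amplitude * exp(-0.5 * ((tt[i] - uk) / pulse_width)^2)
  }
  if (noise_sd > 0) x <- x + stats::rnorm(length(x), 0, noise_sd)
  attr(x, "fs") <- fs
  x
}

#' Synthetic BOLD dataset with planted autonomic coupling
#'
#' Builds a toy 4D BOLD dataset on a small voxel grid: voxels inside
#' `active_mask` receive `effect * reg` (the standardized, convolved
#' regressor) on top of AR(1) noise; all other in-mask voxels are pure
#' AR(1) noise.  The AR(1) coefficient (default 0.3) approximates
#' residual autocorrelation of cleaned resting-state data.
#'
#' @param reg A convolved [regressor_series()].
#' @param dims Grid dimensions, length 3; default `c(20, 20, 10)`.
#' @param active_mask Logical array of dimension `dims` (or `NULL` for no
#'   active voxels) marking coupled voxels.
#' @param effect Scalar effect size (signal amplitude per unit regressor).
#' @param noise_ar1 AR(1) coefficient, |.| < 1; default 0.3.
#' @param noise_sd Marginal noise standard deviation; default 1.
#' @param mask Logical analysis mask; default all voxels.
#' @return A list of class `bold_dataset`: `data` (volumes x voxels
#'   matrix, in-mask columns), `dims`, `mask`, `tr`, `truth` (active
#'   mask + effect).
#' @export
synth_bold <- function(reg, dims = c(20, 20, 10), active_mask = NULL,
                       effect = 1, noise_ar1 = 0.3, noise_sd = 1,
                       mask = NULL) {
  stopifnot(inherits(reg, "regressor_series"))
  if (!isTRUE(reg$convolved))
    stop("`reg` must be HRF-convolved first", call. = FALSE)
  if (abs(noise_ar1) >= 1) stop("|noise_ar1| must be < 1", call. = FALSE)
  if (is.null(mask)) mask <- array(TRUE, dims)
  if (is.null(active_mask)) active_mask <- array(FALSE, dims)
  stopifnot(all(dim(mask) == dims), all(dim(active_mask) == dims))
  n_t <- reg$n_vols
  vox <- which(mask)
  V <- length(vox)
  innov_sd <- noise_sd * sqrt(1 - noise_ar1^2)
  E <- matrix(stats::rnorm(n_t * V, 0, innov_sd), n_t, V)
  if (noise_ar1 != 0) {
    E <- apply(E, 2, function(e)
      as.numeric(stats::filter(e, noise_ar1, method = "recursive")))
  }
  r <- reg$values
  r[is.na(r)] <- 0
  act_cols <- which(vox %in% which(active_mask))
  if (length(act_cols)) E[, act_cols] <- E[, act_cols] + effect * r
  structure(list(data = E, dims = dims, mask = mask, tr = reg$tr,
                 truth = list(active_mask = active_mask, effect = effect,
                              noise_ar1 = noise_ar1, noise_sd = noise_sd)),
            class = "bold_dataset")
}

#' Named synthetic study scenarios
#'
#' Complete synthetic subject bundles at the study's temporal structure:
#' a 900 s recording with baseline heart period 0.9 s, LF modulation
#' (0.1 Hz, amplitude 0.1) and HF modulation (0.25 Hz, amplitude 0.1).
#' `"sympathetic_activation"` doubles the LF amplitude during the
#' 300-600 s epoch; `"vagal_withdrawal"` halves the HF amplitude there;
#' `"arousal"` does both at once (the classic sympatho-excitatory
#' pattern), which makes one planted BOLD signal detectable as a positive
#' SAI and a negative PAI association simultaneously.
#'
#' @param name One of `"baseline"`, `"sympathetic_activation"`,
#'   `"vagal_withdrawal"`, `"arousal"`.
#' @param seed RNG seed for reproducibility.
#' @param duration Recording length (s); default 900.
#' @param ppg If `TRUE` (default) also synthesize the pulse waveform.
#' @param fs PPG sampling rate (Hz); default 400.
#' @param ppg_noise_sd PPG noise level; default 0.05 (5% of pulse
#'   amplitude).
#' @return List with `events` (true beat series), `ppg` (waveform or
#'   `NULL`), `epoch` (the modulated epoch, s), `spec` (modulation
#'   settings), `name`, `seed`.
#' @export
scenario <- function(name = c("baseline", "sympathetic_activation",
                              "vagal_withdrawal", "arousal"),
                     seed = 1, duration = 900, ppg = TRUE, fs = 400,
                     ppg_noise_sd = 0.05) {
  name <- match.arg(name)
  set.seed(seed)
  epoch <- c(duration / 3, 2 * duration / 3)
  scales <- switch(name,
    baseline = NULL,
    sympathetic_activation = data.frame(start = epoch[1], end = epoch[2],
                                        lf_scale = 2, hf_scale = 1),
    vagal_withdrawal = data.frame(start = epoch[1], end = epoch[2],
                                  lf_scale = 1, hf_scale = 0.5),
    arousal = data.frame(start = epoch[1], end = epoch[2],
                         lf_scale = 2, hf_scale = 0.5))
  ev <- simulate_ipfm(duration = duration, mean_hp = 0.9,
                      lf = c(0.1, 0.1), hf = c(0.25, 0.1), epochs = scales,
                      jitter_sd = 0.005)
  wave <- if (ppg) synth_ppg(ev, fs = fs, noise_sd = ppg_noise_sd) else NULL
  list(events = ev, ppg = wave, epoch = epoch,
       spec = attr(ev, "truth"), name = name, seed = seed)
}
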