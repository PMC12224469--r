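# Shared fixtures, all generated in code.

# Benchmark parameter set for within-class simulations: mixed
# slow-plus-oscillatory dynamics with zero net DC gain (so the baseline
# g0 equals the mean heart period and every parameter direction is well
# identified).  Heart-period CV about 3%, mean 0.85 s: realistic resting
# HRV.
study_params <- function(basis = laguerre_basis()) {
  S <- colSums(basis$Phi)
  v <- c(0.45, 0.18, 0.12, 0.06, 0.03, 0.01, 0, 0, 0, 0)
  g1 <- v - sum(v * S) / sum(S * S) * S
  list(g0 = 0.85, g1 = g1, xi0 = 1000, basis = basis)
}

# small regular event series with optional tampering
regular_events <- function(n = 30, hp = 1, extra_at = NULL, drop_at = NULL) {
  u <- seq(0, by = hp, length.out = n)
  if (!is.null(drop_at)) u <- setdiff(u, drop_at)
  if (!is.null(extra_at)) u <- sort(c(u, extra_at))
  event_series(u)
}

# brute-force Laguerre filter output via the scalar phi evaluator
brute_laguerre_outputs <- function(ev, basis, t) {
  u <- ev$u
  hp <- c(NA, diff(u))
  Ntil <- sum(u < t)
  n_lags <- min(Ntil - 1L, basis$N_max)
  vapply(0:basis$J_max, function(j) {
    s <- 0
    for (n in 0:(n_lags - 1L)) {
      k <- Ntil - n
      if (k >= 2) s <- s + laguerre_phi(basis, j, n) * hp[k]
    }
    s
  }, numeric(1))
}
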