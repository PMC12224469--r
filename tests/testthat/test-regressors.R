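fake_series <- function(times, values) {
  df <- data.frame(time = times, sai = values, pai = values,
                   mu_hp = 0.9, converged = !is.na(values))
  attr(df, "step") <- median(diff(times))
  class(df) <- c("instantaneous_series", "data.frame")
  df
}

test_that("resampling is exact on constants and affine functions of time", {
  tt <- seq(0, 900, by = 0.005)
  const <- fake_series(tt, rep(2.5, length(tt)))
  r <- resample_at_volumes(const, "sai", tr = 0.72, n_vols = 1200,
                           offset = 0)
  expect_equal(length(r$values), 1200)
  expect_true(all(r$values == 2.5))
  ramp <- fake_series(tt, tt)
  r2 <- resample_at_volumes(ramp, "sai", tr = 0.72, n_vols = 1200,
                            offset = 0)
  expect_equal(r2$values, (0:1199) * 0.72, tolerance = 1e-9)
  expect_equal(max((0:1199) * 0.72), 863.28)
})

test_that("resampling flags coverage failures and blanks long gaps", {
  tt <- seq(0, 100, by = 0.005)
  s <- fake_series(tt, sin(tt))
  expect_error(resample_at_volumes(s, "sai", tr = 0.72, n_vols = 1200,
                                   offset = 0), "covers")
  v <- sin(tt)
  v[tt > 40 & tt < 45] <- NA           # 5-s gap: beyond the bridge limit
  v[tt > 70 & tt < 70.5] <- NA         # 0.5-s gap: bridged
  s2 <- fake_series(tt, v)
  r <- resample_at_volumes(s2, "sai", tr = 0.72, n_vols = 130, offset = 0)
  vt <- (0:129) * 0.72
  expect_true(all(is.na(r$values[vt > 40 & vt < 45])))
  expect_true(all(!is.na(r$values[vt > 69 & vt < 72])))
})

test_that("double-gamma kernel is peak-normalized with canonical shape", {
  h <- double_gamma_hrf(dt = 0.1)
  expect_equal(max(h$weights), 1)
  expect_equal(h$t[which.max(h$weights)], 6, tolerance = 0.11)
  expect_equal(h$weights[1], 0)
  expect_lt(abs(h$weights[length(h$weights)]), 0.01)
  expect_lt(min(h$weights), 0)         # undershoot present
  expect_error(double_gamma_hrf(dt = -1), "positive")
})

test_that("convolution has the right impulse response, linearity and causality", {
  hrf <- double_gamma_hrf(dt = 0.72)
  imp <- regressor_series(c(1, rep(0, 99)), tr = 0.72)
  out <- convolve_regressor(imp, hrf, standardize = FALSE)
  nk <- length(hrf$weights)
  expect_equal(out$values[seq_len(nk)], hrf$weights, tolerance = 1e-9)
  expect_lt(max(abs(out$values[-seq_len(nk)])), 1e-12)

  set.seed(5)
  x <- regressor_series(rnorm(100), tr = 0.72)
  y <- regressor_series(rnorm(100), tr = 0.72)
  ax_by <- regressor_series(2 * x$values - 3 * y$values, tr = 0.72)
  lhs <- convolve_regressor(ax_by, hrf, standardize = FALSE)$values
  rhs <- 2 * convolve_regressor(x, hrf, standardize = FALSE)$values -
    3 * convolve_regressor(y, hrf, standardize = FALSE)$values
  expect_equal(lhs, rhs, tolerance = 1e-9)

  # causality: changing the input after volume v leaves outputs <= v alone
  x2 <- x; x2$values[60:100] <- x2$values[60:100] + 5
  o1 <- convolve_regressor(x, hrf, standardize = FALSE)$values
  o2 <- convolve_regressor(x2, hrf, standardize = FALSE)$values
  expect_equal(o1[1:59], o2[1:59], tolerance = 1e-12)
})

test_that("standardization and missing-volume handling behave", {
  set.seed(6)
  v <- rnorm(200); v[50:60] <- NA
  out <- convolve_regressor(regressor_series(v, tr = 0.72))
  expect_true(all(is.na(out$values[50:60])))
  expect_equal(mean(out$values, na.rm = TRUE), 0, tolerance = 1e-9)
  expect_equal(sd(out$values, na.rm = TRUE), 1, tolerance = 1e-9)
  expect_error(convolve_regressor(regressor_series(rep(NA_real_, 10))),
               "missing")
})
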